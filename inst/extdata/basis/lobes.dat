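# Fitted lobe-function parameters, version 1.
# Generated by fit_lobe_p_orbital / fit_abs_lobe_representation from the
# STO-6G reference tabulation; keyed by element + principal quantum number.
element n_quantum k alpha1 alpha2 alpha3 A1 A2 A3 absA1 absA2 absA3 absA4 absA5 absA6 absax1 absax2 absax3 absax4 absax5 absax6 absap1 absap2 absap3 absap4 absap5 absap6 absx01 absx02 absx03 absx04 absx05 absx06
C 2 0.0200000000533  1.898841089157 0.534751107638 0.1994023451630  7.23852805918  6.74230456682 1.532025736474 9.55628273189e-01 0.2608380729869 0.0116961971135 0.2715364489232 0.1015433422475 6.21341635594e-03   99959.88823972   9.18349794933  6.83017181083  2.257366856776  0.848575584197 0.656985793640628 4.59611389227e+04  1.574031482914 0.118009997714 0.600314052844 0.275295429541 9.69129555444e-02 -5.91681672497 0.486598254051 0.617231818590 0.987121076418 1.852250630592  3.52429064677
N 2 0.0681577537875  2.915656240940 0.824736963137 0.2915453911711  2.22623671574  2.58775458262 0.799716474370 1.15358137923e+00 0.3148692356988 0.0141189995905 0.3277837209796 0.1225774834081 7.50049115403e-03  128480.75827116  11.80376249803  8.77897793636  2.901445875562  1.090693841580 0.844439048770248 5.90749157866e+04  2.023139101381 0.151680981810 0.771597548462 0.353843588252 1.24564465146e-01 -5.21893577629 0.429204613696 0.544430116740 0.870691410722 1.633780042883  3.10860508233
O 2 0.0681586569411  3.881781076881 1.098018753534 0.3881511234763  2.75923593403  3.20729516904 0.991171959197 1.42978289674e+00 0.3902582479373 0.0174995058841 0.4062648431434 0.1519261600939 9.29633068136e-03  171054.26416401  15.71506843231 11.68798839003  3.862871732189  1.452107187178 1.124253172711648 7.86500358995e+04  2.693528392460 0.201942135775 1.027274843789 0.471093535188 1.65840264435e-01 -4.52307767023 0.371977331659 0.471839434241 0.754599222199 1.415942703031  2.69412440317
P 2 0.0681525624153 22.566618630388 6.383303358031 2.2565061792181 10.33123336920 12.00890478678 3.711220546598 5.35298386264e+00 1.4610932248810 0.0655166408939 1.5210205369435 0.5687984414644 3.48046603668e-02  994416.57304870  91.35887124512 67.94761543919 22.456637891046  8.441762383594 6.535797237858444 4.57228585043e+05 15.658710915684 1.173981879919 5.972017913334 2.738681909721 9.64105210936e-01 -1.87593083138 0.154276312703 0.195693774613 0.312967419413 0.587257342399  1.11737878497
P 3 0.0201234753938  0.429509343294 0.191054564431 0.0937320951471  3.51989351151  2.89760056177 0.387800324246 2.19987506573e-05 0.0611934025045 0.1691295502662 0.0926760123571 0.0110974600821 6.61604435093e-12    8035.78088139   2.70380712065  2.03193843542  0.528074544806  0.431496395265 0.000611991301440 8.15241044098e-05  0.430442986413 0.340648110758 0.160251308402 0.134403401414 1.34269684579e+04  8.96974195582 1.934106800607 1.004754486658 2.161681859567 4.219190675592 -2.77545266232
S 2 0.0681554775996 26.918125811707 7.614176072603 2.6916191631872 11.79143223967 13.70624451182 4.235755524885 6.10982614323e+00 1.6676727993479 0.0747798416027 1.7360730537346 0.6492191415225 3.97255865647e-02 1186166.29155703 108.97526895939 81.04970613930 26.786869416704 10.069556614543 7.796071165860948 5.45394304373e+05 18.678122992738 1.400356521201 7.123580331786 3.266771947141 1.15001010011e+00 -1.71762443193 0.141257214570 0.179179532011 0.286556666691 0.537699760707  1.02308521651
S 3 0.0200004556954  0.553417071812 0.246674880380 0.1215593695063  4.28433024153  3.51727378337 0.481799827268 2.66160049144e-05 0.0740371090687 0.2046276632335 0.1121275130015 0.0134266739363 8.00466679683e-12   10359.87591399   3.48579766905  2.61961225256  0.680803376583  0.556293057048 0.000788990396446 1.05102368787e-04  0.554934983059 0.439169784478 0.206598922320 0.173275327142 1.73102936949e+04  7.89981126156 1.703402256135 0.884905145310 1.903831657836 3.715916263575 -2.44439051934
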