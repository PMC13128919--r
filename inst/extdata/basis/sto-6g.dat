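! STO-6G tabulation, GENERATED by this package's overlap-maximizing
! Slater-fit code (fit_sto_expansion / fit_sto_expansion_sp, shared
! sp exponents per the standard minimal-basis convention): universal
! zeta = 1 expansions scaled by per-shell Slater exponents (H 1.24;
! He 1.69; C 5.67/1.72; N 6.67/1.95; O 7.66/2.25; P 14.70/5.425/1.60;
! S 15.70/5.925/1.8167). Synthetic stand-in for the published tables;
! primarily the reference target of the p-orbital lobe fit.
H 0
S 6 1.00
        35.51752382      0.00916424
         6.51311195      0.04936072
         1.82212624      0.16854043
         0.62595354      0.37056130
         0.24307410      0.41649978
         0.10010902      0.13032532
****
He 0
S 6 1.00
        65.97398528      0.00916424
        12.09813934      0.04936072
         3.38460897      0.16854043
         1.16271196      0.37056130
         0.45151140      0.41649978
         0.18595303      0.13032532
****
C 0
S 6 1.00
       742.61792496      0.00916424
       136.17936058      0.04936072
        38.09791512      0.16854043
        13.08774575      0.37056130
         5.08231328      0.41649978
         2.09312890      0.13032532
SP 6 1.00
        30.49727377     -0.01325272      0.00375965
         6.03623214     -0.04699151      0.03767913
         1.87605113     -0.03378582      0.17389644
         0.72178369      0.25024137      0.41803636
         0.31347095      0.59511741      0.42586002
         0.14368663      0.24070661      0.10170848
****
N 0
S 6 1.00
      1027.66360908      0.00916424
       188.45030328      0.04936072
        52.72137883      0.16854043
        18.11133232      0.37056130
         7.03310307      0.41649978
         2.89655330      0.13032532
SP 6 1.00
        39.19885191     -0.01325272      0.00375965
         7.75850889     -0.04699151      0.03767913
         2.41133194     -0.03378582      0.17389644
         0.92772529      0.25024137      0.41803636
         0.40291146      0.59511741      0.42586002
         0.18468375      0.24070661      0.10170848
****
O 0
S 6 1.00
      1355.36681871      0.00916424
       248.54367303      0.04936072
        69.53326640      0.16854043
        23.88670637      0.37056130
         9.27583156      0.41649978
         3.82021140      0.13032532
SP 6 1.00
        52.18782059     -0.01325272      0.00375965
        10.32937574     -0.04699151      0.03767913
         3.21035318     -0.03378582      0.17389644
         1.23513722      0.25024137      0.41803636
         0.53642059      0.59511741      0.42586002
         0.24588073      0.24070661      0.10170848
****
P 0
S 6 1.00
      4991.53337766      0.00916424
       915.33452243      0.04936072
       256.07652136      0.16854043
        87.96975880      0.37056130
        34.16095346      0.41649978
        14.06904201      0.13032532
SP 6 1.00
       303.39164000     -0.01325272      0.00375965
        60.04937953     -0.04699151      0.03767913
        18.66324948     -0.03378582      0.17389644
         7.18041686      0.25024137      0.41803636
         3.11845790      0.59511741      0.42586002
         1.42941703      0.24070661      0.10170848
SP 6 1.00
         7.88512106     -0.00794326     -0.00713948
         2.11171513     -0.07100390     -0.01829266
         0.79191325     -0.17850353      0.07621903
         0.35447572      0.15107276      0.41451406
         0.17541231      0.73549055      0.48895792
         0.09040166      0.27605323      0.10587889
****
S 0
S 6 1.00
      5693.75289120      0.00916424
      1044.10572647      0.04936072
       292.10191009      0.16854043
       100.34553124      0.37056130
        38.96678893      0.41649978
        16.04830471      0.13032532
SP 6 1.00
       361.89354259     -0.01325272      0.00375965
        71.62848221     -0.04699151      0.03767913
        22.26201576     -0.03378582      0.17389644
         8.56499044      0.25024137      0.41803636
         3.71977876      0.59511741      0.42586002
         1.70504630      0.24070661      0.10170848
SP 6 1.00
        10.16564250     -0.00794326     -0.00713948
         2.72246183     -0.07100390     -0.01829266
         1.02094907     -0.17850353      0.07621903
         0.45699659      0.15107276      0.41451406
         0.22614477      0.73549055      0.48895792
         0.11654747      0.27605323      0.10587889
****
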