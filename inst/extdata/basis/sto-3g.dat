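! STO-3G minimal basis, Gaussian-dialect tabulation.
! H, He, C, N, O: standard published exponents/contractions
! (coefficients refer to normalized primitives; SP shells share exponents).
! P, S (third row): GENERATED tabulation - universal STO-3G expansions
! produced by this package's overlap-maximizing Slater fits (shared sp
! exponents), scaled by Slater-rule exponents (zeta 1s/2sp/3sp:
! P 14.70/5.425/1.6000, S 15.70/5.925/1.8167). Synthetic stand-in.
H 0
S 3 1.00
      3.42525091             0.15432897
      0.62391373             0.53532814
      0.16885540             0.44463454
****
He 0
S 3 1.00
      6.36242139             0.15432897
      1.15892300             0.53532814
      0.31364979             0.44463454
****
C 0
S 3 1.00
     71.61683700             0.15432897
     13.04509600             0.53532814
      3.53051220             0.44463454
SP 3 1.00
      2.94124940            -0.09996723             0.15591627
      0.68348310             0.39951283             0.60768372
      0.22228990             0.70011547             0.39195739
****
N 0
S 3 1.00
     99.10616900             0.15432897
     18.05231200             0.53532814
      4.88566020             0.44463454
SP 3 1.00
      3.78045590            -0.09996723             0.15591627
      0.87849660             0.39951283             0.60768372
      0.28571440             0.70011547             0.39195739
****
O 0
S 3 1.00
    130.70932000             0.15432897
     23.80886100             0.53532814
      6.44360830             0.44463454
SP 3 1.00
      5.03315130            -0.09996723             0.15591627
      1.16959610             0.39951283             0.60768372
      0.38038900             0.70011547             0.39195739
****
P 0
S 3 1.00
       481.37697161      0.15432865
        87.68322471      0.53532751
        23.73052004      0.44463547
SP 3 1.00
        29.25971257     -0.09996726      0.15591740
         6.79938789      0.39951272      0.60768195
         2.21137800      0.70011565      0.39195774
SP 3 1.00
         1.23610692     -0.21962026      0.01058751
         0.34487073      0.22559486      0.59516671
         0.13498005      0.90039888      0.46200139
****
S 0
S 3 1.00
       549.09810604      0.15432865
       100.01868693      0.53532751
        27.06897999      0.44463547
SP 3 1.00
        34.90175616     -0.09996726      0.15591740
         8.11048904      0.39951272      0.60768195
         2.63778995      0.70011565      0.39195774
SP 3 1.00
         1.59361169     -0.21962026      0.01058751
         0.44461366      0.22559486      0.59516671
         0.17401875      0.90039888      0.46200139
****
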