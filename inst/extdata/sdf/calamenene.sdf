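Calamenene
     RDKit          2D

 37 38  0  0  0  0  0  0  0  0999 V2000
    2.2026   -2.6432    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7344   -2.3364    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7503   -2.5503    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6779   -1.3715    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1208    0.0212    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5891    0.3280    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.0574    0.6347    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2824    1.7963    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3638    0.2351    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9209    1.6278    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4056    1.8417    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9627    3.2345    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3332    0.6629    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7761   -0.7298    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2914   -0.9437    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.6709   -2.9499    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7315   -1.5493    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.8959   -4.1115    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6872   -3.8357    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2818   -3.9753    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0723   -3.2591    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6777   -2.4897    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4016   -1.0372    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8913    1.5035    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8461   -0.4267    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.5257    0.9415    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9319    2.1295    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3642   -0.8336    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9756    3.2646    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.7023    2.2797    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7876    1.6708    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0067    2.8066    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.5197    4.6272    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3554    2.6774    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5699    3.7915    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8178    0.8769    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7037   -1.9086    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  6  8  1  0
  5  9  1  0
  9 10  2  0
 10 11  1  0
 11 12  1  0
 11 13  2  0
 13 14  1  0
 14 15  2  0
 15  2  1  0
 15  9  1  0
  1 16  1  0
  1 17  1  0
  1 18  1  0
  2 19  1  0
  3 20  1  0
  3 21  1  0
  4 22  1  0
  4 23  1  0
  5 24  1  0
  6 25  1  0
  7 26  1  0
  7 27  1  0
  7 28  1  0
  8 29  1  0
  8 30  1  0
  8 31  1  0
 10 32  1  0
 12 33  1  0
 12 34  1  0
 12 35  1  0
 13 36  1  0
 14 37  1  0
M  END
$$$$
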