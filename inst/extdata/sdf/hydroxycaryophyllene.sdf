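14-Hydroxy-9-epi-(E)-caryophyllene
     RDKit          2D

 40 41  0  0  0  0  0  0  0  0999 V2000
   -4.2020    1.8082    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9892    0.9256    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4037   -0.5159    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7947   -1.8867    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4470   -2.5453    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0087   -2.1835    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8466   -3.4277    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8913   -0.9707    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3878   -0.8672    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2843    0.6292    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1808    2.1257    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.7807    0.7327    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.2771    0.8362    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.7878    0.5258    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2533    1.6056    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7450    1.7635    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.4149    2.6908    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4739    3.1196    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.0846    0.5954    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.9002   -0.6194    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2177   -3.3258    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2826   -2.0770    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6829   -3.8361    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3225   -3.7633    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.1880   -4.7754    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3430   -3.3242    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.4521   -2.3619    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.2722   -0.9142    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6729   -2.3398    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0773    3.6221    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0504    2.2940    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.3086    2.2802    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8277    1.6172    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.9491   -0.1368    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.1150   -0.4080    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.1059    1.3524    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3481    3.1026    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8737    2.5954    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7798    2.8494    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3389    3.2075    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  3
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  2  0
  6  8  1  0
  8  9  1  0
  9 10  1  0
 10 11  1  0
 10 12  1  0
 12 13  1  0
 10 14  1  0
 14 15  1  0
 15 16  1  0
 16  2  1  0
 14  8  1  0
  1 17  1  0
  1 18  1  0
  1 19  1  0
  3 20  1  0
  4 21  1  0
  4 22  1  0
  5 23  1  0
  5 24  1  0
  7 25  1  0
  7 26  1  0
  8 27  1  0
  9 28  1  0
  9 29  1  0
 11 30  1  0
 11 31  1  0
 11 32  1  0
 12 33  1  0
 12 34  1  0
 13 35  1  0
 14 36  1  0
 15 37  1  0
 15 38  1  0
 16 39  1  0
 16 40  1  0
M  END
$$$$
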