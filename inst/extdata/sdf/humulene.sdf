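Humulene
     RDKit          2D

 39 39  0  0  0  0  0  0  0  0999 V2000
   -0.7312   -0.2554    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1565   -1.6938    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1039   -2.5072    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3673   -1.6986    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9930   -0.3353    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7454    0.9624    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4653   -0.6219    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0128    0.8002    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8021    2.2853    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6363    2.7106    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6207    1.5788    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8121    0.3154    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0608    1.1589    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2770   -0.3254    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6564   -1.6910    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1337    1.1205    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6447   -0.8528    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2107   -0.0086    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5238   -3.9472    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8314   -2.0248    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.7182   -3.1569    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.4978    2.2600    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1251    0.3737    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.4478    1.7148    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.9377   -0.9085    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.9293    0.8045    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.3603   -2.1182    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3528    0.1796    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6154    3.5457    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0278    3.2707    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5622    4.2088    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.1444   -0.8400    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1647   -0.3331    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5404    0.9640    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4240    1.7846    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3646   -1.3585    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.6090    0.3644    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1685   -3.1094    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8373   -2.6161    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  5  7  1  0
  5  8  1  0
  8  9  2  0
  9 10  1  0
 10 11  1  0
 11 12  1  0
 11 13  2  0
 13 14  1  0
 14 15  1  0
 15  2  1  0
  1 16  1  0
  1 17  1  0
  1 18  1  0
  3 19  1  0
  4 20  1  0
  4 21  1  0
  6 22  1  0
  6 23  1  0
  6 24  1  0
  7 25  1  0
  7 26  1  0
  7 27  1  0
  8 28  1  0
  9 29  1  0
 10 30  1  0
 10 31  1  0
 12 32  1  0
 12 33  1  0
 12 34  1  0
 13 35  1  0
 14 36  1  0
 14 37  1  0
 15 38  1  0
 15 39  1  0
M  END
$$$$
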