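Caryophyllene oxide
     RDKit          2D

 40 42  0  0  0  0  0  0  0  0999 V2000
    2.3791   -2.0387    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4706   -0.5415    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.9678   -0.6331    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5621    0.9557    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0649    1.0472    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9734   -0.4500    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0591   -1.5381    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5495   -1.7079    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8003   -0.8800    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3984   -2.2556    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2589   -0.5299    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2264    0.5582    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6283    1.9338    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2859    2.6031    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1727    2.2530    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0005    3.5038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2875   -3.5359    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.2500   -2.2001    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5082   -2.2002    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.4650   -0.7246    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.0219   -1.5171    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1292    0.2378    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.4462    1.0098    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8355    2.4306    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6146    2.4429    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2980   -1.2741    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0758   -2.5189    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1419   -3.0358    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1318   -3.1486    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5756   -2.8020    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9965   -3.6312    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.7740   -1.6575    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1060   -3.0169    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.5688    1.2274    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.0848    2.2924    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0627    3.3695    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1711    3.8141    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5321    3.9000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3312    4.8462    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4978    3.4123    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  2  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  7  8  1  0
  8  9  1  0
  9 10  1  0
  9 11  1  0
 11 12  1  0
 12 13  1  0
 13 14  1  0
 14 15  1  0
 15 16  2  0
  6  2  1  0
 12  9  1  0
 15  5  1  0
  1 17  1  0
  1 18  1  0
  1 19  1  0
  3 20  1  0
  3 21  1  0
  3 22  1  0
  4 23  1  0
  4 24  1  0
  5 25  1  0
  6 26  1  0
  7 27  1  0
  7 28  1  0
  8 29  1  0
  8 30  1  0
 10 31  1  0
 10 32  1  0
 10 33  1  0
 12 34  1  0
 13 35  1  0
 13 36  1  0
 14 37  1  0
 14 38  1  0
 16 39  1  0
 16 40  1  0
M  END
$$$$
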