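Caryophyllene
     RDKit          2D

 39 40  0  0  0  0  0  0  0  0999 V2000
   -3.9996    1.8972    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8089    0.9849    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2590   -0.4460    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6840   -1.8314    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3530   -2.5231    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1112   -2.1974    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9181   -3.4619    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0236   -1.0067    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5221   -0.9403    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4556    0.5582    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3891    2.0568    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.9541    0.6247    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9571    0.4918    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0571    1.5970    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5444    1.7917    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1902    2.8096    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2392    3.1902    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.9119    0.7066    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.7575   -0.5124    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1424   -3.2596    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.1761   -1.9849    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6210   -3.8324    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2583   -3.7191    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2264   -4.7929    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4166   -3.3955    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5498   -2.4114    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.4051   -1.0092    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7707   -2.4195    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3227    3.5553    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.2626    2.2036    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5211    2.2328    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.4527    0.6912    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.0230    1.5078    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1010   -0.2488    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2955    1.3103    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1148    3.0959    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0941    2.5587    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5521    2.9029    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1027    3.2252    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
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
 10 13  1  0
 13 14  1  0
 14 15  1  0
 15  2  1  0
 13  8  1  0
  1 16  1  0
  1 17  1  0
  1 18  1  0
  3 19  1  0
  4 20  1  0
  4 21  1  0
  5 22  1  0
  5 23  1  0
  7 24  1  0
  7 25  1  0
  8 26  1  0
  9 27  1  0
  9 28  1  0
 11 29  1  0
 11 30  1  0
 11 31  1  0
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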