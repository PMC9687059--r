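element	rho_cnt	zeta	atomic_number
H	2.15	3.7795	1
C	797.4	6.1415	6
N	1293.7	7.3699	7
O	1964.6	8.5983	8
S	16643.6	6.8668	16
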