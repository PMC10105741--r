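CTRL1_c1
CTRL1_c2
CTRL1_c3
CTRL1_c4
CTRL1_c5
CTRL1_c6
CTRL1_c7
CTRL1_c8
CTRL1_c9
CTRL1_c10
CTRL1_c11
CTRL1_c12
CTRL1_c13
CTRL1_c14
CTRL1_c15
CTRL1_c16
CTRL1_c17
CTRL1_c18
CTRL1_c19
CTRL1_c20
HSCR1_c1
HSCR1_c2
HSCR1_c3
HSCR1_c4
HSCR1_c5
HSCR1_c6
HSCR1_c7
HSCR1_c8
HSCR1_c9
HSCR1_c10
HSCR1_c11
HSCR1_c12
HSCR1_c13
HSCR1_c14
HSCR1_c15
HSCR1_c16
HSCR1_c17
HSCR1_c18
HSCR1_c19
HSCR1_c20
HSCR2_c1
HSCR2_c2
HSCR2_c3
HSCR2_c4
HSCR2_c5
HSCR2_c6
HSCR2_c7
HSCR2_c8
HSCR2_c9
HSCR2_c10
HSCR2_c11
HSCR2_c12
HSCR2_c13
HSCR2_c14
HSCR2_c15
HSCR2_c16
HSCR2_c17
HSCR2_c18
HSCR2_c19
HSCR2_c20
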