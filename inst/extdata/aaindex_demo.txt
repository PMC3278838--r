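H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
R LIT:0902099b PMID:7108955
A Kyte, J. and Doolittle, R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500
    3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200
//
H HOPT810101
D Hydrophilicity value (Hopp-Woods, 1981)
R LIT:0727023b PMID:6167991
A Hopp, T.P. and Woods, K.R.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   -0.500   3.000   0.200   3.000  -1.000   0.200   3.000   0.000  -0.500  -1.800
   -1.800   3.000  -1.300  -2.500   0.000   0.300  -0.400  -3.400  -2.300  -1.500
//
H GRAR740102
D Polarity (Grantham, 1974)
R LIT:2004143b PMID:4843792
A Grantham, R.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    8.100  10.500  11.600  13.000   5.500  10.500  12.300   9.000  10.400   5.200
    4.900  11.300   5.700   5.200   8.000   9.200   8.600   5.400   6.200   5.900
//
H SYNPART01
D Synthetic test record with partial data (missing-value marker)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.100   0.200      NA   0.400   0.500   0.600   0.700   0.800   0.900   1.000
    1.100   1.200   1.300   1.400   1.500   1.600   1.700   1.800   1.900   2.000
//
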