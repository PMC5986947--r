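H SYNPROP1
D Synthetic hydropathy-like scale (test fixture, not a real AAindex entry)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H SYNPROP2
D Synthetic bulkiness-like scale (test fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    11.5    14.3    12.8    11.7    13.5    14.5    13.6     3.4    13.7    21.4
    21.4    15.7    16.3    19.8    17.4     9.5    15.8    21.7    18.0    21.6
//
H SYNPROP3
D Synthetic scale with one missing residue value (test fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.3     NA      0.9     1.2     0.1     0.7     1.1     0.2     0.8     0.4
     0.5     1.0     0.6     0.3     0.4     0.6     0.5     0.2     0.7     0.4
//
H SYNPROP4
D Synthetic degenerate scale, all residues equal (test fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0
     2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0
//
H SYNPROP5
D Synthetic scale with two missing residue values (test fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     5.0     4.0     NA      2.0     1.0     6.0     7.0     8.0     NA      9.0
     3.0     2.5     4.5     6.5     7.5     1.5     2.2     8.8     6.6     4.4
//
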