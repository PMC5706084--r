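point_id,campaign_id
A101,C1
A201,C1
A301,C1
A401,C1
B101,C1
B201,C1
B301,C1
C1,C1
C2,C1
C3,C1
C4,C1
D1,C1
D2,C1
D3,C1
D4,C1
E1,C1
E2,C1
E3,C1
E4,C1
F1,C1
F2,C1
F3,C1
F4,C1
F5,C1
A1,C2
A2,C2
A3,C2
A4,C2
B1,C2
B2,C2
B3,C2
B4,C2
B5,C2
B6,C2
B7,C2
B8,C2
B9,C2
E301,C2
E501,C2
G101,C2
INT701,C2
INT801,C2
INT1,C2
INT1bis,C2
INT2,C2
INT2bis,C2
INT3,C2
INT4,C2
F2bis,C2
F4bis,C2
F5bis,C2
G1,C2
G2,C2
G3,C2
G4,C2
G5,C2
H1,C2
H2,C2
H3,C2
H4,C2
H5,C2
L1,C3
L2,C3
L3,C3
L4,C3
L5,C3
L6,C3
L7,C3
L8,C3
L9,C3
L10,C3
A3,C4
B2,C4
B7,C4
B8,C4
B9,C4
E301,C4
E501,C4
G101,C4
INT701,C4
INT801,C4
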