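UUU  26.2 (   1309)  UUC  23.8 (   1191)  UUA   8.7 (    435)  UUG   6.9 (    345)
UCU   9.2 (    461)  UCC  11.8 (    592)  UCA  10.2 (    512)  UCG   4.6 (    230)
UAU  29.6 (   1480)  UAC  20.4 (   1020)  UGU  26.0 (   1302)  UGC  24.0 (   1198)
UGG  50.0 (   2500)  CUU   9.8 (    490)  CUC  10.3 (    513)  CUA   5.8 (    289)
CUG   8.5 (    427)  CCU  14.1 (    703)  CCC   8.7 (    433)  CCA   6.3 (    315)
CCG  21.0 (   1050)  CAU  20.1 (   1003)  CAC  29.9 (   1497)  CAA  29.9 (   1496)
CAG  20.1 (   1004)  CGU   7.3 (    367)  CGC   7.4 (    369)  CGA   7.1 (    356)
CGG  10.5 (    526)  AUU  11.0 (    551)  AUC  15.5 (    775)  AUA  23.5 (   1174)
AUG  50.0 (   2500)  ACU  15.9 (    795)  ACC   6.6 (    329)  ACA  14.1 (    705)
ACG  13.4 (    672)  AAU  20.2 (   1012)  AAC  29.8 (   1488)  AAA  22.4 (   1122)
AAG  27.6 (   1378)  AGU   3.2 (    159)  AGC  10.9 (    546)  AGA  10.8 (    539)
AGG   6.9 (    344)  GUU  12.5 (    623)  GUC  17.6 (    879)  GUA  11.0 (    549)
GUG   9.0 (    448)  GCU  10.8 (    540)  GCC   8.5 (    424)  GCA  12.2 (    610)
GCG  18.5 (    926)  GAU  12.5 (    624)  GAC  37.5 (   1876)  GAA  17.1 (    853)
GAG  32.9 (   1647)  GGU  14.3 (    717)  GGC   7.5 (    374)  GGA  12.1 (    605)
GGG  16.1 (    803)
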