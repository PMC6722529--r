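UUU  11.7 (    587)  UUC  38.3 (   1913)  UUA   3.2 (    160)  UUG  15.1 (    757)
UCU   4.4 (    219)  UCC  10.0 (    500)  UCA   4.9 (    244)  UCG  13.8 (    689)
UAU  13.7 (    686)  UAC  36.3 (   1814)  UGU  15.2 (    759)  UGC  34.8 (   1741)
UGG  50.0 (   2500)  CUU   4.7 (    237)  CUC  11.8 (    590)  CUA   4.3 (    216)
CUG  10.8 (    540)  CCU   7.7 (    387)  CCC  17.2 (    859)  CCA   6.1 (    306)
CCG  19.0 (    949)  CAU  14.3 (    715)  CAC  35.7 (   1785)  CAA  15.1 (    755)
CAG  34.9 (   1745)  CGU   4.9 (    247)  CGC  12.1 (    605)  CGA   5.2 (    260)
CGG  12.3 (    617)  AUU  10.8 (    540)  AUC  28.7 (   1434)  AUA  10.5 (    526)
AUG  50.0 (   2500)  ACU   6.3 (    314)  ACC  14.9 (    745)  ACA   5.9 (    296)
ACG  22.9 (   1145)  AAU  12.8 (    641)  AAC  37.2 (   1859)  AAA  11.2 (    560)
AAG  38.8 (   1940)  AGU   4.7 (    236)  AGC  12.2 (    611)  AGA   4.1 (    207)
AGG  11.3 (    563)  GUU   7.9 (    393)  GUC  17.3 (    866)  GUA   4.8 (    239)
GUG  20.1 (   1003)  GCU  10.6 (    530)  GCC  14.4 (    719)  GCA   5.8 (    291)
GCG  19.2 (    960)  GAU  16.6 (    831)  GAC  33.4 (   1669)  GAA   9.4 (    472)
GAG  40.6 (   2028)  GGU   9.0 (    448)  GGC  15.3 (    763)  GGA   7.2 (    362)
GGG  18.5 (    926)
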