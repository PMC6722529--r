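UUU  34.9 (   1747)  UUC  15.1 (    753)  UUA  11.6 (    579)  UUG   5.5 (    277)
UCU   8.9 (    443)  UCC   5.4 (    269)  UCA  13.9 (    696)  UCG   6.0 (    301)
UAU  30.2 (   1508)  UAC  19.8 (    992)  UGU  35.9 (   1797)  UGC  14.1 (    703)
UGG  50.0 (   2500)  CUU  11.7 (    585)  CUC   4.8 (    242)  CUA  10.0 (    499)
CUG   6.3 (    317)  CCU  17.1 (    854)  CCC   7.7 (    386)  CCA  16.0 (    801)
CCG   9.2 (    459)  CAU  34.6 (   1732)  CAC  15.4 (    768)  CAA  32.8 (   1640)
CAG  17.2 (    860)  CGU  11.0 (    552)  CGC   5.0 (    251)  CGA  13.1 (    653)
CGG   5.3 (    263)  AUU  24.5 (   1227)  AUC   7.4 (    370)  AUA  18.1 (    904)
AUG  50.0 (   2500)  ACU  17.3 (    865)  ACC   7.3 (    366)  ACA  18.7 (    937)
ACG   6.6 (    332)  AAU  33.4 (   1669)  AAC  16.6 (    831)  AAA  35.3 (   1764)
AAG  14.7 (    736)  AGU  11.5 (    574)  AGC   4.4 (    218)  AGA  10.0 (    502)
AGG   5.6 (    278)  GUU  18.6 (    928)  GUC   5.0 (    252)  GUA  18.4 (    919)
GUG   8.0 (    401)  GCU  16.3 (    815)  GCC   7.1 (    356)  GCA  18.7 (    937)
GCG   7.9 (    393)  GAU  35.2 (   1762)  GAC  14.8 (    738)  GAA  35.0 (   1752)
GAG  15.0 (    748)  GGU  17.7 (    885)  GGC   6.5 (    325)  GGA  17.5 (    875)
GGG   8.3 (    415)
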