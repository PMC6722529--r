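id	host	group
cp_001	pepino	GP1
cp_002	pepino	GP2
cp_003	pepino	GP1
cp_004	pepino	GP2
cp_005	pepino	GP1
cp_006	pepino	GP2
cp_007	pepino	GP1
cp_008	pepino	GP2
cp_009	pepino	GP1
cp_010	pepino	GP2
cp_011	potato	GP1
cp_012	potato	GP2
cp_013	potato	GP1
cp_014	potato	GP2
cp_015	potato	GP1
cp_016	potato	GP2
cp_017	potato	GP1
cp_018	potato	GP2
cp_019	potato	GP1
cp_020	potato	GP2
cp_021	tomato	GP1
cp_022	tomato	GP2
cp_023	tomato	GP1
cp_024	tomato	GP2
cp_025	tomato	GP1
cp_026	tomato	GP2
cp_027	tomato	GP1
cp_028	tomato	GP2
cp_029	tomato	GP1
cp_030	tomato	GP2
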