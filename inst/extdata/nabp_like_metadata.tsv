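id	host	group
nabp_001	pepino	GP1
nabp_002	pepino	GP2
nabp_003	pepino	GP1
nabp_004	pepino	GP2
nabp_005	pepino	GP1
nabp_006	pepino	GP2
nabp_007	pepino	GP1
nabp_008	pepino	GP2
nabp_009	pepino	GP1
nabp_010	pepino	GP2
nabp_011	potato	GP1
nabp_012	potato	GP2
nabp_013	potato	GP1
nabp_014	potato	GP2
nabp_015	potato	GP1
nabp_016	potato	GP2
nabp_017	potato	GP1
nabp_018	potato	GP2
nabp_019	potato	GP1
nabp_020	potato	GP2
nabp_021	tomato	GP1
nabp_022	tomato	GP2
nabp_023	tomato	GP1
nabp_024	tomato	GP2
nabp_025	tomato	GP1
nabp_026	tomato	GP2
nabp_027	tomato	GP1
nabp_028	tomato	GP2
nabp_029	tomato	GP1
nabp_030	tomato	GP2
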