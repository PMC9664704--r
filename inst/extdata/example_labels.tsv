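sample_id	group
sample_001	A
sample_002	A
sample_003	A
sample_004	A
sample_005	A
sample_006	A
sample_007	A
sample_008	A
sample_009	A
sample_010	A
sample_011	B
sample_012	B
sample_013	B
sample_014	B
sample_015	B
sample_016	B
sample_017	B
sample_018	B
sample_019	B
sample_020	B
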