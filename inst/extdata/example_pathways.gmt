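SYNP0001	SYNP0001	CHEBI:00012	CHEBI:00020	CHEBI:00014	CHEBI:00030
SYNP0002	SYNP0002	CHEBI:00021	CHEBI:00012	CHEBI:00005	CHEBI:00039	CHEBI:00036
SYNP0003	SYNP0003	CHEBI:00050	CHEBI:00022	CHEBI:00048	CHEBI:00053	CHEBI:00049	CHEBI:00024
SYNP0004	SYNP0004	CHEBI:00050	CHEBI:00015	CHEBI:00060	CHEBI:00037
SYNP0005	SYNP0005	CHEBI:00051	CHEBI:00020	CHEBI:00005	CHEBI:00029
SYNP0006	SYNP0006	CHEBI:00050	CHEBI:00011	CHEBI:00058	CHEBI:00032	CHEBI:00045	CHEBI:00057	CHEBI:00018	CHEBI:00046
SYNP0007	SYNP0007	CHEBI:00040	CHEBI:00016	CHEBI:00010	CHEBI:00007	CHEBI:00025
SYNP0008	SYNP0008	CHEBI:00016	CHEBI:00058	CHEBI:00047	CHEBI:00030	CHEBI:00052	CHEBI:00019	CHEBI:00049	CHEBI:00053
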