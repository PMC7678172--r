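animal_id	location	origin	phenotype	18:14705518:T:C
D001	Edersee	G	WT	TC
D002	Edersee	G	WT	TC
D003	Edersee	G	WT	TT
D004	Edersee	G	WT	TT
D005	Edersee	G	WT	TT
D006	Edersee	G	WT	TT
D007	Edersee	G	WT	TT
D008	Edersee	G	WT	TT
D009	Edersee	G	WT	TT
D010	Edersee	G	dark pigmented	TT
D011	Edersee	G	white	CC
D012	Edersee	G	white	CC
D013	Edersee	G	white	CC
D014	Eulbach	G	WT	TC
D015	Eulbach	G	WT	TC
D016	Eulbach	G	WT	TT
D017	Eulbach	G	WT	TT
D018	Eulbach	G	WT	TT
D019	Eulbach	G	WT	TT
D020	Eulbach	G	WT	TT
D021	Eulbach	G	WT	TT
D022	Eulbach	G	WT	TT
D023	Eulbach	G	dark pigmented	TT
D024	Eulbach	G	white	CC
D025	Eulbach	G	white	CC
D026	Griebelschied	G	white	CC
D027	Griebelschied	G	white	CC
D028	Hanstedt	G	WT	TC
D029	Hanstedt	G	white	CC
D030	Hanstedt	G	white	CC
D031	Hanstedt	G	white	CC
D032	Hanstedt	G	white	CC
D033	Hanstedt	G	white	CC
D034	Murowana	H	WT	TC
D035	Murowana	H	WT	TC
D036	Murowana	H	WT	TT
D037	Murowana	H	WT	TT
D038	Murowana	H	WT	TT
D039	Murowana	H	WT	TT
D040	Murowana	H	WT	TT
D041	Murowana	H	WT	TT
D042	Murowana	H	WT	TT
D043	Murowana	H	dark pigmented	TT
D044	Murowana	H	white	CC
D045	Weishauswald	G	WT	TC
D046	Weishauswald	G	WT	TT
D047	Weishauswald	G	WT	TT
D048	Weishauswald	G	WT	TT
D049	Weishauswald	G	dark pigmented	TT
D050	Weishauswald	G	white	CC
D051	Mueritz	H	WT	TT
D052	Mueritz	H	WT	TT
D053	Mueritz	H	white	CC
D054	Neuruppin	H	WT	TT
D055	Neuruppin	H	WT	TT
D056	Neuruppin	H	WT	TT
D057	Neuruppin	H	WT	TT
D058	Neuruppin	H	WT	TT
D059	Neuruppin	H	WT	TT
D060	Neuruppin	H	WT	TT
D061	Neuruppin	H	WT	TT
D062	Neuruppin	H	WT	TT
D063	Neuruppin	H	WT	TT
D064	Neuruppin	H	WT	TT
D065	Neuruppin	H	WT	TT
D066	Neuruppin	H	dark pigmented	TT
D067	Pleizenhausen	G	white	CC
D068	Sababurg	G	WT	TC
D069	Sababurg	G	WT	TC
D070	Sababurg	G	WT	TC
D071	Sababurg	G	WT	TT
D072	Sababurg	G	WT	TT
D073	Sababurg	G	WT	TT
D074	Sababurg	G	WT	TT
D075	Sababurg	G	WT	TT
D076	Sababurg	G	WT	TT
D077	Sababurg	G	WT	TT
D078	Sababurg	G	WT	TT
D079	Sababurg	G	WT	TT
D080	Sababurg	G	WT	TT
D081	Sababurg	G	WT	TT
D082	Sababurg	G	WT	TT
D083	Sababurg	G	WT	TT
D084	Sababurg	G	WT	TT
D085	Sababurg	G	WT	TT
D086	Sababurg	G	WT	TT
D087	Sababurg	G	WT	TT
D088	Sababurg	G	WT	TT
D089	Sababurg	G	WT	TT
D090	Sababurg	G	WT	TT
D091	Sababurg	G	dark pigmented	TT
D092	Sababurg	G	white	CC
D093	Sababurg	G	white	CC
D094	Sababurg	G	white	CC
D095	Sababurg	G	white	CC
D096	Sababurg	G	white	CC
D097	Weilburg	G	WT	TT
D098	Weilburg	G	WT	TT
D099	Wolfshagen	H	WT	TT
D100	Wolfshagen	H	WT	TT
D101	Wolfshagen	H	dark pigmented	TT
D102	Wolfshagen	H	white	CC
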