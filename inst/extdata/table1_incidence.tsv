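agent_id	event_id	link_type
i	e001	a1
i	e002	a1
i	e003	a2
i	e004	a1
i	e005	a3
i	e006	a3
i	e007	a3
i	e011	a2
i	e012	a2
i	e013	a2
i	e014	a2
i	e015	a2
i	e016	a2
i	e017	a2
i	e018	a2
i	e019	a2
i	e020	a2
i	e021	a2
i	e022	a2
i	e023	a2
i	e024	a2
i	e031	a1
i	e032	a2
i	e033	a2
i	e034	a2
i	e035	a2
i	e036	a2
i	e037	a3
i	e038	a3
i	e039	a3
i	e040	a3
i	e041	a3
i	e042	a3
i	e043	a3
i	e044	a3
i	e045	a3
i	e046	a3
i	e047	a3
i	e048	a3
i	e049	a3
j	e001	a1
j	e002	a1
j	e003	a1
j	e004	a2
j	e005	a2
j	e006	a2
j	e007	a2
j	e008	a2
j	e009	a2
j	e010	a2
j	e011	a3
j	e012	a3
j	e013	a3
j	e014	a3
j	e015	a3
j	e016	a3
j	e017	a3
j	e018	a3
j	e019	a3
j	e020	a3
j	e021	a3
j	e022	a3
j	e023	a3
j	e024	a3
j	e025	a3
j	e026	a3
j	e027	a3
j	e028	a3
j	e029	a3
j	e030	a3
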