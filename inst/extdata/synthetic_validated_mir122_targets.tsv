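gene_id	detected_by_clip
synGene001	TRUE
synGene002	TRUE
synGene003	TRUE
synGene004	TRUE
synGene005	TRUE
synGene006	TRUE
synGene007	TRUE
synGene008	TRUE
synGene009	TRUE
synGene010	TRUE
synGene011	TRUE
synGene012	TRUE
synGene013	TRUE
synGene014	TRUE
synGene015	TRUE
synGene016	TRUE
synGene017	TRUE
synGene018	TRUE
synGene019	TRUE
synGene020	TRUE
synGene021	TRUE
synGene022	FALSE
synGene023	FALSE
synGene024	FALSE
synGene025	FALSE
synGene026	FALSE
synGene027	FALSE
synGene028	FALSE
synGene029	FALSE
synGene030	FALSE
synGene031	FALSE
synGene032	FALSE
synGene033	FALSE
synGene034	FALSE
synGene035	FALSE
synGene036	FALSE
synGene037	FALSE
synGene038	FALSE
synGene039	FALSE
synGene040	FALSE
synGene041	FALSE
synGene042	FALSE
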