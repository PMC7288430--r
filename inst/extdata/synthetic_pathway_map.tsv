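ko_id	map_id	map_name	category
K00001	map00701	Folate biosynthesis	Metabolic pathways
K00002	map00702	Folate biosynthesis	Metabolic pathways
K00003	map00703	Folate biosynthesis	Metabolic pathways
K00004	map00704	Folate biosynthesis	Metabolic pathways
K00005	map00705	Sulfur relay system	Sulfur relay system
K00006	map00706	Cysteine metabolism	Metabolic pathways
K00007	map00707	Ubiquinone biosynthesis	Metabolic pathways
K00008	map00708	Ubiquinone biosynthesis	Metabolic pathways
K00009	map03001	Transcription machinery	Genetic information processing
K00010	map03002	Transcription machinery	Genetic information processing
K00011	map03003	Transcription machinery	Genetic information processing
K00012	map03004	Transcription machinery	Genetic information processing
K00013	map03005	Transcription machinery	Genetic information processing
K00014	map03006	Transcription machinery	Genetic information processing
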