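# Demonstration pathway catalog: a small curated set of freshwater-relevant
# metabolic pathways. Each step lists annotation-id synonyms across the four
# annotation systems (KO/COG/PFAM/TIGR); any synonym satisfies the step.
# Steps flagged unique are diagnostic for the pathway. This is a
# demonstration catalog, not a curation of KEGG or MetaCyc content.
pathways:
  - pathway_id: nitrogen_fixation
    provenance: nifHDKEB, Mo-Fe nitrogenase and cofactor biosynthesis
    steps:
      - step_id: nifH
        annotation_ids: ["TIGR:TIGR1287", "KO:K02588"]
        unique: true
      - step_id: nifD
        annotation_ids: ["TIGR:TIGR1282", "KO:K02586"]
        unique: true
      - step_id: nifK
        annotation_ids: ["TIGR:TIGR1286", "KO:K02591"]
        unique: true
      - step_id: nifE
        annotation_ids: ["KO:K02587", "PFAM:PF00142"]
        unique: false
      - step_id: nifB
        annotation_ids: ["KO:K02585", "COG:COG0535"]
        unique: false
  - pathway_id: assimilatory_sulfate_reduction
    provenance: sat/cysNC, cysC, cysH, sir
    steps:
      - step_id: sulfate_adenylyltransferase
        annotation_ids: ["KO:K00958", "COG:COG2046"]
        unique: false
      - step_id: adenylylsulfate_kinase
        annotation_ids: ["KO:K00860", "PFAM:PF01583"]
        unique: false
      - step_id: PAPS_reductase
        annotation_ids: ["KO:K00390", "COG:COG0175"]
        unique: true
      - step_id: sulfite_reductase_assim
        annotation_ids: ["KO:K00380", "KO:K00381", "TIGR:TIGR2910"]
        unique: true
  - pathway_id: dissimilatory_sulfate_reduction
    provenance: sat, aprAB, dsrAB
    steps:
      - step_id: sulfate_adenylyltransferase
        annotation_ids: ["KO:K00958", "COG:COG2046"]
        unique: false
      - step_id: APS_reductase
        annotation_ids: ["KO:K00394", "KO:K00395", "TIGR:TIGR2061"]
        unique: true
      - step_id: dissimilatory_sulfite_reductase
        annotation_ids: ["KO:K11180", "KO:K11181", "TIGR:TIGR2064"]
        unique: true
  - pathway_id: cbb_carbon_fixation
    provenance: Calvin-Benson-Bassham cycle key enzymes
    steps:
      - step_id: rubisco_large_subunit
        annotation_ids: ["KO:K01601", "TIGR:TIGR3326"]
        unique: true
      - step_id: phosphoribulokinase
        annotation_ids: ["KO:K00855", "PFAM:PF00485"]
        unique: true
      - step_id: fructose_bisphosphatase
        annotation_ids: ["KO:K03841", "COG:COG0158"]
        unique: false
      - step_id: transketolase
        annotation_ids: ["KO:K00615", "COG:COG0021"]
        unique: false
  - pathway_id: polyamine_synthesis
    provenance: arginine decarboxylase route to spermidine
    steps:
      - step_id: arginine_decarboxylase
        annotation_ids: ["KO:K01585", "PFAM:PF02784"]
        unique: false
      - step_id: agmatinase
        annotation_ids: ["KO:K01480", "COG:COG0010"]
        unique: false
      - step_id: SAM_decarboxylase
        annotation_ids: ["KO:K01611", "PFAM:PF02675"]
        unique: true
      - step_id: spermidine_synthase
        annotation_ids: ["KO:K00797", "COG:COG0421"]
        unique: true
  - pathway_id: polyamine_degradation
    provenance: putrescine/spermidine gamma-glutamylation route
    steps:
      - step_id: glutamylputrescine_synthase
        annotation_ids: ["KO:K09470", "COG:COG0174"]
        unique: true
      - step_id: glutamylputrescine_oxidase
        annotation_ids: ["KO:K09471", "PFAM:PF01266"]
        unique: false
      - step_id: aminobutyraldehyde_dehydrogenase
        annotation_ids: ["KO:K09472", "COG:COG1012"]
        unique: false
      - step_id: glutamylaminobutyrate_hydrolase
        annotation_ids: ["KO:K09473", "PFAM:PF04952"]
        unique: false
  - pathway_id: sox_thiosulfate_oxidation
    provenance: soxABXYZ thiosulfate oxidation complex
    steps:
      - step_id: soxB
        annotation_ids: ["KO:K17224", "TIGR:TIGR4486"]
        unique: true
      - step_id: soxA
        annotation_ids: ["KO:K17222", "TIGR:TIGR4484"]
        unique: false
      - step_id: soxY
        annotation_ids: ["KO:K17226", "PFAM:PF13501"]
        unique: false
      - step_id: soxZ
        annotation_ids: ["KO:K17227", "PFAM:PF08770"]
        unique: false
  - pathway_id: xylose_degradation
    provenance: xylose isomerase route
    steps:
      - step_id: xylose_isomerase
        annotation_ids: ["KO:K01805", "COG:COG2115"]
        unique: true
      - step_id: xylulokinase
        annotation_ids: ["KO:K00854", "PFAM:PF02782"]
        unique: false
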