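rule_id,GH,PRL,TSH,monomorphous,immature,acidophil_stem_cell_features,type,warning
PIT1_ASC,*,*,*,*,*,true,acidophil_stem_cell,
PIT1_IMMATURE_FLAG,*,*,*,*,true,*,immature_PIT1,
PIT1_GH_ONLY,+,-,-,*,*,*,somatotroph,
PIT1_PRL_ONLY,-,+,-,*,*,*,lactotroph,
PIT1_TSH_ONLY,-,-,+,*,*,*,thyrotroph,
PIT1_GH_PRL_MONO,+,+,-,true,*,*,mammosomatotroph,
PIT1_GH_PRL_DIMORPH,+,+,-,false,*,*,mixed_somatotroph_lactotroph,
PIT1_GH_PRL_FLAG_UNKNOWN,+,+,-,na,*,*,mammosomatotroph,monomorphous flag unknown; mammosomatotroph assumed over mixed somatotroph-lactotroph
PIT1_HORMONE_SILENT,-,-,-,*,*,*,immature_PIT1,hormone-silent PIT1 tumour; immature PIT1 lineage assumed
PIT1_MULTIHORMONE_MATURE,*,*,*,*,*,*,mature_plurihormonal_PIT1,
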