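character,applicability
temporal_smooth,all
head_smooth,all
nasal_rostral_contact,all
dorsal_mucronate,all
precloacal_pores,adult-males-only
preocular_color,all
head_dots,all
interparietal_line,all
paravertebral_marks,all
lateral_field_marks,all
dorsolateral_stripes,all
vertebral_line,all
throat_marks,all
melanistic_belly,adult-males-only
ringed_tail,adult-males-only
antehumeral_fold,all
neck_folds,all
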