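subcategory,category
attention,M+
responsivity,M+
pos_affective_comm,M+
structuring_pos,M+
structuring_task,M+
structuring_neg,M-
covert_hostility,M-
overt_hostility,M-
noncontingent,M-
engagement,C+
positive_affect,C+
involving_pos,C+
involving_neg,C-
controlling,C-
avoidant,C-
resistant,C-
MAlone,MAlone
CAlone,CAlone
Together,Together
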