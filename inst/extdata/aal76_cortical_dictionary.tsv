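roi_name	hemisphere	lobe
Precentral	L	frontal
Precentral	R	frontal
Frontal_Sup	L	frontal
Frontal_Sup	R	frontal
Frontal_Sup_Orb	L	frontal
Frontal_Sup_Orb	R	frontal
Frontal_Mid	L	frontal
Frontal_Mid	R	frontal
Frontal_Mid_Orb	L	frontal
Frontal_Mid_Orb	R	frontal
Frontal_Inf_Oper	L	frontal
Frontal_Inf_Oper	R	frontal
Frontal_Inf_Tri	L	frontal
Frontal_Inf_Tri	R	frontal
Frontal_Inf_Orb	L	frontal
Frontal_Inf_Orb	R	frontal
Rolandic_Oper	L	frontal
Rolandic_Oper	R	frontal
Supp_Motor_Area	L	frontal
Supp_Motor_Area	R	frontal
Frontal_Sup_Medial	L	frontal
Frontal_Sup_Medial	R	frontal
Frontal_Med_Orb	L	frontal
Frontal_Med_Orb	R	frontal
Rectus	L	frontal
Rectus	R	frontal
Paracentral_Lobule	L	frontal
Paracentral_Lobule	R	frontal
Postcentral	L	parietal
Postcentral	R	parietal
Parietal_Sup	L	parietal
Parietal_Sup	R	parietal
Parietal_Inf	L	parietal
Parietal_Inf	R	parietal
SupraMarginal	L	parietal
SupraMarginal	R	parietal
Angular	L	parietal
Angular	R	parietal
Precuneus	L	parietal
Precuneus	R	parietal
ParaHippocampal	L	temporal
ParaHippocampal	R	temporal
Fusiform	L	temporal
Fusiform	R	temporal
Heschl	L	temporal
Heschl	R	temporal
Temporal_Sup	L	temporal
Temporal_Sup	R	temporal
Temporal_Pole_Sup	L	temporal
Temporal_Pole_Sup	R	temporal
Temporal_Mid	L	temporal
Temporal_Mid	R	temporal
Temporal_Pole_Mid	L	temporal
Temporal_Pole_Mid	R	temporal
Temporal_Inf	L	temporal
Temporal_Inf	R	temporal
Calcarine	L	occipital
Calcarine	R	occipital
Cuneus	L	occipital
Cuneus	R	occipital
Lingual	L	occipital
Lingual	R	occipital
Occipital_Sup	L	occipital
Occipital_Sup	R	occipital
Occipital_Mid	L	occipital
Occipital_Mid	R	occipital
Occipital_Inf	L	occipital
Occipital_Inf	R	occipital
Insula	L	insula_cingulate
Insula	R	insula_cingulate
Cingulum_Ant	L	insula_cingulate
Cingulum_Ant	R	insula_cingulate
Cingulum_Mid	L	insula_cingulate
Cingulum_Mid	R	insula_cingulate
Cingulum_Post	L	insula_cingulate
Cingulum_Post	R	insula_cingulate
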