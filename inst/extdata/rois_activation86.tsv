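roi	label	hemisphere	n_units	inferred
L_bankssts	bankssts	left	805	TRUE
L_caudalanteriorcingulate	caudalanteriorcingulate	left	805	TRUE
L_caudalmiddlefrontal	caudalmiddlefrontal	left	805	TRUE
L_cuneus	cuneus	left	805	TRUE
L_entorhinal	entorhinal	left	805	TRUE
L_frontalpole	frontalpole	left	805	TRUE
L_fusiform	fusiform	left	805	TRUE
L_inferiorparietal	inferiorparietal	left	805	TRUE
L_inferiortemporal	inferiortemporal	left	805	TRUE
L_insula	insula	left	805	TRUE
L_isthmuscingulate	isthmuscingulate	left	805	TRUE
L_lateraloccipital	lateraloccipital	left	805	TRUE
L_lateralorbitofrontal	lateralorbitofrontal	left	805	TRUE
L_lingual	lingual	left	805	TRUE
L_medialorbitofrontal	medialorbitofrontal	left	805	TRUE
L_middletemporal	middletemporal	left	805	TRUE
L_paracentral	paracentral	left	805	TRUE
L_parahippocampal	parahippocampal	left	805	TRUE
L_parsopercularis	parsopercularis	left	805	TRUE
L_parsorbitalis	parsorbitalis	left	805	TRUE
L_parstriangularis	parstriangularis	left	805	TRUE
L_pericalcarine	pericalcarine	left	805	TRUE
L_posteriorcingulate	posteriorcingulate	left	805	TRUE
L_precuneus	precuneus	left	805	TRUE
L_rostralanteriorcingulate	rostralanteriorcingulate	left	805	TRUE
L_rostralmiddlefrontal	rostralmiddlefrontal	left	805	TRUE
L_superiorfrontal	superiorfrontal	left	4486	FALSE
L_superiorparietal	superiorparietal	left	805	TRUE
L_supramarginal	supramarginal	left	805	TRUE
L_temporalpole	temporalpole	left	805	TRUE
L_vPreC	vPreC	left	805	TRUE
L_dPreC	dPreC	left	805	TRUE
L_vPostC	vPostC	left	805	TRUE
L_dPostC	dPostC	left	805	TRUE
L_HG	HG	left	805	TRUE
L_HS	HS	left	805	TRUE
L_PT	PT	left	805	TRUE
L_pSTG	pSTG	left	805	TRUE
L_aSTG	aSTG	left	805	TRUE
L_LF	LF	left	805	TRUE
L_iCS	iCS	left	805	TRUE
L_STS	STS	left	805	TRUE
L_PP	PP	left	805	TRUE
R_bankssts	bankssts	right	805	TRUE
R_caudalanteriorcingulate	caudalanteriorcingulate	right	805	TRUE
R_caudalmiddlefrontal	caudalmiddlefrontal	right	805	TRUE
R_cuneus	cuneus	right	805	TRUE
R_entorhinal	entorhinal	right	805	TRUE
R_frontalpole	frontalpole	right	805	TRUE
R_fusiform	fusiform	right	805	TRUE
R_inferiorparietal	inferiorparietal	right	805	TRUE
R_inferiortemporal	inferiortemporal	right	805	TRUE
R_insula	insula	right	805	TRUE
R_isthmuscingulate	isthmuscingulate	right	805	TRUE
R_lateraloccipital	lateraloccipital	right	805	TRUE
R_lateralorbitofrontal	lateralorbitofrontal	right	805	TRUE
R_lingual	lingual	right	805	TRUE
R_medialorbitofrontal	medialorbitofrontal	right	805	TRUE
R_middletemporal	middletemporal	right	805	TRUE
R_paracentral	paracentral	right	805	TRUE
R_parahippocampal	parahippocampal	right	805	TRUE
R_parsopercularis	parsopercularis	right	805	TRUE
R_parsorbitalis	parsorbitalis	right	805	TRUE
R_parstriangularis	parstriangularis	right	805	TRUE
R_pericalcarine	pericalcarine	right	805	TRUE
R_posteriorcingulate	posteriorcingulate	right	805	TRUE
R_precuneus	precuneus	right	805	TRUE
R_rostralanteriorcingulate	rostralanteriorcingulate	right	805	TRUE
R_rostralmiddlefrontal	rostralmiddlefrontal	right	805	TRUE
R_superiorfrontal	superiorfrontal	right	805	TRUE
R_superiorparietal	superiorparietal	right	805	TRUE
R_supramarginal	supramarginal	right	805	TRUE
R_temporalpole	temporalpole	right	805	TRUE
R_vPreC	vPreC	right	805	TRUE
R_dPreC	dPreC	right	805	TRUE
R_vPostC	vPostC	right	805	TRUE
R_dPostC	dPostC	right	805	TRUE
R_HG	HG	right	805	TRUE
R_HS	HS	right	86	FALSE
R_PT	PT	right	805	TRUE
R_pSTG	pSTG	right	805	TRUE
R_aSTG	aSTG	right	805	TRUE
R_LF	LF	right	805	TRUE
R_iCS	iCS	right	805	TRUE
R_STS	STS	right	805	TRUE
R_PP	PP	right	805	TRUE
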