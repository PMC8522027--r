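# Reference sentences for Jaccard similarity features: unusual but decisive
# result phrasings observed during error analysis on training data.
sentence_id	language	text
ref_cerb2_neg	fr	CerB2 négatif
ref_er_plus	nl	ER: +
ref_rp_neg	fr	RP négatifs
ref_her2_2plus	nl	HER2 score 2+
ref_no_ampl_nl	nl	geen amplificatie van het HER2 gen
ref_no_ampl_fr	fr	pas d'amplification du gène HER2
ref_fish_ongoing	nl	FISH wordt uitgevoerd
ref_hr_pos_nl	nl	hormoonreceptoren positief
ref_hr_pos_fr	fr	récepteurs hormonaux positifs
ref_allred	nl	Allred score 8/8
ref_pos_control	nl	positieve controle 3+
ref_fish_equiv	fr	résultat FISH équivoque
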