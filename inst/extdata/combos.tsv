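# Boolean combinations of base features (AND/OR/comparisons); each
# expression evaluates to 0/1 per report.
name	expression
zero_dominates	regex.report.ihc_score_0.count > max(regex.report.ihc_score_1.count, regex.report.ihc_score_2.count, regex.report.ihc_score_3.count)
one_dominates	regex.report.ihc_score_1.count > max(regex.report.ihc_score_0.count, regex.report.ihc_score_2.count, regex.report.ihc_score_3.count)
two_dominates	regex.report.ihc_score_2.count > max(regex.report.ihc_score_0.count, regex.report.ihc_score_1.count, regex.report.ihc_score_3.count)
three_dominates	regex.report.ihc_score_3.count > max(regex.report.ihc_score_0.count, regex.report.ihc_score_1.count, regex.report.ihc_score_2.count)
er_negated	(regex.seg_er.er_mention.presence > 0) & (regex.seg_er.negation.presence > 0)
pr_negated	(regex.seg_pr.pr_mention.presence > 0) & (regex.seg_pr.negation.presence > 0)
her2_negated	(regex.seg_her2.her2_mention.presence > 0) & (regex.seg_her2.negation.presence > 0)
er_pos_unnegated	(regex.seg_er.positive_term.presence > 0) & (regex.seg_er.negation.count == 0)
pr_pos_unnegated	(regex.seg_pr.positive_term.presence > 0) & (regex.seg_pr.negation.count == 0)
her2_amplified_unnegated	(regex.report.amplified.presence > 0) & (regex.report.not_amplified.presence == 0)
ratio_high	num.report.ratio.value > 2.2
ratio_low	(num.report.ratio.present > 0) & (num.report.ratio.value < 1.8)
ratio_equivocal	(num.report.ratio.value >= 1.8) & (num.report.ratio.value <= 2.2)
allred_high	num.report.allred.value >= 3
allred_low	(num.report.allred.present > 0) & (num.report.allred.value <= 2)
ish_ongoing_no_result	(regex.report.ongoing_term.presence > 0) & (regex.report.amplified.presence == 0) & (regex.report.not_amplified.presence == 0) & (regex.report.equivocal_term.presence == 0)
control_with_3plus	(regex.report.positive_control.presence > 0) & (regex.report.ihc_score_3.presence > 0)
multiple_ihc_scores	(regex.report.ihc_score_0.presence + regex.report.ihc_score_1.presence + regex.report.ihc_score_2.presence + regex.report.ihc_score_3.presence) > 1
late_positive_in_er_segment	(loc.report.positive_term.last_rel > 0.5) & (regex.seg_er.positive_term.presence > 0)
negative_in_conclusion	(regex.report.conclusion_marker.presence > 0) & (regex.report.negative_term.presence > 0)
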