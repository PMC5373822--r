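expression_class	occupancy_class	n
unchanged	unchanged	8125
unchanged	reduced_global	378
unchanged	reduced_tss_gt_body	11
unchanged	reduced_tss_lt_body	16
unchanged	increased_global	256
unchanged	increased_tss_gt_body	10
unchanged	increased_tss_lt_body	3
down	unchanged	549
down	reduced_global	324
down	reduced_tss_gt_body	15
down	reduced_tss_lt_body	33
down	increased_global	3
up	unchanged	634
up	reduced_global	6
up	increased_global	200
up	increased_tss_gt_body	13
up	increased_tss_lt_body	2
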