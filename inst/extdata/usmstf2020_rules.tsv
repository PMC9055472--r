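priority	rule_id	interval_group	condition	description
1	carcinoma_refer	refer	carcinoma_present	Colorectal carcinoma: refer for individualized management outside the interval groups
2	adenoma_count_gt10	y1	n_adenomas > 10	More than 10 adenomas: repeat in 1 year
3	high_risk_neoplasia	y3	n_adenomas >= 5 | ge(max_adenoma_size_mm, 10) | any_villous_or_hgd | ge(max_ssl_size_mm, 10) | any_ssl_dysplasia | any_tsa | n_ssls >= 5	5-10 adenomas, adenoma >=10 mm, villous/tubulovillous features or high-grade dysplasia, SSL >=10 mm or with dysplasia, TSA, or 5-10 SSLs: 3 years
4	intermediate_count	y3_5	n_adenomas >= 3 | n_ssls >= 3 | any_hp_ge10mm	3-4 small adenomas, 3-4 small SSLs, or hyperplastic polyp >=10 mm: 3-5 years
5	low_risk_ssl	y5_10	n_ssls >= 1	1-2 SSLs < 10 mm: 5-10 years
6	low_risk_adenoma	y7_10	n_adenomas >= 1	1-2 tubular adenomas < 10 mm: 7-10 years
7	no_neoplasia	y10	TRUE	No adenoma or SSL: 10 years
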