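surface_form	language	canonical	category
# Anatomical segments (left colon: rectum through splenic flexure)
rectum	en	segment_rectum	location
rectosigmoid	en	segment_rectosigmoid	location
rectosigmoid junction	en	segment_rectosigmoid	location
rs junction	abbrev	segment_rectosigmoid	location
sigmoid	en	segment_sigmoid	location
sigmoid colon	en	segment_sigmoid	location
s-colon	abbrev	segment_sigmoid	location
descending	en	segment_descending	location
descending colon	en	segment_descending	location
d-colon	abbrev	segment_descending	location
splenic flexure	en	segment_splenic_flexure	location
sf	abbrev	segment_splenic_flexure	location
# Anatomical segments (right colon: transverse colon through cecum)
transverse	en	segment_transverse	location
transverse colon	en	segment_transverse	location
t-colon	abbrev	segment_transverse	location
hepatic flexure	en	segment_hepatic_flexure	location
hf	abbrev	segment_hepatic_flexure	location
ascending	en	segment_ascending	location
ascending colon	en	segment_ascending	location
a-colon	abbrev	segment_ascending	location
cecum	en	segment_cecum	location
caecum	en	segment_cecum	location
ileocecal valve	en	segment_ileocecal_valve	location
icv	abbrev	segment_ileocecal_valve	location
# Histology: conventional adenomas
tubular adenoma	en	hist_tubular_adenoma	histology
ta	abbrev	hist_tubular_adenoma	histology
tubulovillous adenoma	en	hist_tubulovillous_adenoma	histology
tva	abbrev	hist_tubulovillous_adenoma	histology
villous adenoma	en	hist_villous_adenoma	histology
adenomatous polyp	en	hist_adenoma_nos	histology
adenoma	en	hist_adenoma_nos	histology
# Histology: serrated polyps
hyperplastic polyp	en	hist_hyperplastic	histology
hp	abbrev	hist_hyperplastic	histology
sessile serrated lesion	en	hist_ssl	histology
sessile serrated adenoma	en	hist_ssl	histology
sessile serrated polyp	en	hist_ssl	histology
sessile serrated adenoma/polyp	en	hist_ssl	histology
ssl	abbrev	hist_ssl	histology
ssa	abbrev	hist_ssl	histology
ssa/p	abbrev	hist_ssl	histology
traditional serrated adenoma	en	hist_tsa	histology
tsa	abbrev	hist_tsa	histology
# Histology: carcinoma
adenocarcinoma	en	hist_carcinoma	histology
carcinoma	en	hist_carcinoma	histology
# Dysplasia grading
high grade dysplasia	en	dysplasia_high	histology
high-grade dysplasia	en	dysplasia_high	histology
hgd	abbrev	dysplasia_high	histology
low grade dysplasia	en	dysplasia_low	histology
low-grade dysplasia	en	dysplasia_low	histology
lgd	abbrev	dysplasia_low	histology
dysplasia	en	dysplasia_nos	histology
# Biopsy markers (evidence that a specimen was taken)
bx	abbrev	marker_biopsy	biopsy_marker
biopsy	en	marker_biopsy	biopsy_marker
biopsied	en	marker_biopsy	biopsy_marker
polypectomy	en	marker_polypectomy	biopsy_marker
emr	abbrev	marker_emr	biopsy_marker
endoscopic mucosal resection	en	marker_emr	biopsy_marker
removed	en	marker_resection	biopsy_marker
resected	en	marker_resection	biopsy_marker
resection	en	marker_resection	biopsy_marker
snared	en	marker_resection	biopsy_marker
cold snare	en	marker_resection	biopsy_marker
excised	en	marker_resection	biopsy_marker
# Size units
mm	en	unit_mm	size_unit
cm	en	unit_cm	size_unit
# Count words
one	en	count_1	count_word
single	en	count_1	count_word
two	en	count_2	count_word
three	en	count_3	count_word
four	en	count_4	count_word
five	en	count_5	count_word
six	en	count_6	count_word
seven	en	count_7	count_word
eight	en	count_8	count_word
nine	en	count_9	count_word
ten	en	count_10	count_word
eleven	en	count_11	count_word
twelve	en	count_12	count_word
# Negation cues
no	en	negation_cue	negation
without	en	negation_cue	negation
negative for	en	negation_cue	negation
free of	en	negation_cue	negation
# Removable noise phrases
see note	en	noise	noise_term
as above	en	noise	noise_term
aforementioned	en	noise	noise_term
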