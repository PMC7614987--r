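# ontology=GOBP
# domain_type=Pfam
# fdr_threshold=NA
# corpus_N=NA
# Synthetic mini reference: GOBP term memberships reconstructed from a
# published worked example (five immune-related terms and the Pfam
# domains overlapping a 33-domain input list). Statistics columns are NA:
# only the memberships are known. Not the production annotation database.
domain_id	domain_type	term_id	term_name	p	fdr	score	origin
PF00001	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00001	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00001	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00001	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF00001	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00008	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00008	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00008	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00017	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00017	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00017	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00017	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF00017	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00018	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00018	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00018	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00018	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF00018	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00020	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00020	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00020	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00020	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF00020	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00023	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00023	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00048	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00048	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00048	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00048	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF00048	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00129	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00129	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00129	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00129	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF00129	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00130	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00130	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00130	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00130	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00169	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00169	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00169	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00169	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00170	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00170	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00178	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00229	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00229	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00229	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00605	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00605	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00605	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF00605	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00619	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00619	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00619	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF00619	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF00619	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00656	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00656	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00969	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00969	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00969	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF00993	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF00993	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF00993	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF01017	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF01017	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF01017	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF01023	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF01023	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF01023	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF01108	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF01108	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF01108	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF01582	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF01582	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF01582	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF01582	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF01582	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF02198	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF02864	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF02864	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF02864	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF02865	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF02865	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF02865	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF07654	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF07654	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF07654	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF07654	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF07654	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF07686	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF07686	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF07686	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF07714	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF07714	Pfam	GO:0002684	positive regulation of immune system process	NA	NA	NA	direct
PF07714	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF07714	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF07714	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF07716	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF07716	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF07716	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
PF09294	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF09294	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF10401	Pfam	GO:0002376	immune system process	NA	NA	NA	direct
PF10401	Pfam	GO:0006950	response to stress	NA	NA	NA	direct
PF10401	Pfam	GO:0006952	defense response	NA	NA	NA	direct
PF10401	Pfam	GO:0048522	positive regulation of cellular process	NA	NA	NA	direct
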