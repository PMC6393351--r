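# Naming variants -> canonical compound names (case-insensitive).
# "β-Selinene (a)"/"β-Selinene (b)" are the two distinct rows labelled
# β-Selinene in the packaged heterologous product table, kept separate to
# preserve the printed layout.
alias	compound
β-selinene (a)	β-selinene
β-selinene (b)	β-selinene
(e)-caryophyllene	(E)-β-caryophyllene
trans-β-farnesene	(E)-β-farnesene
valencene	(+)-valencene
aromadendrene	(+)-aromadendrene
bergamotene	α-bergamotene
β-farnesene	(E)-β-farnesene
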