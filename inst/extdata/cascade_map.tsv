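# Compound -> carbocation cascade class assignments for grapevine flower
# sesquiterpenes and heterologous TPS products.
# Classes: farnesyl (direct deprotonation, linear farnesenes),
# humulyl (1,11-ring closure), germacradienyl (1,10-ring closure),
# nerolidyl_bisabolyl (FPP -> NPP isomerization branch).
# Assignments for γ-cadinene, α-amorphene and camphene are provisional:
# mechanistic routes via alternative cations have been proposed for all
# three; edit this table rather than the code to change them.
compound	cascade
(E)-β-farnesene	farnesyl
(E,E)-α-farnesene	farnesyl
β-caryophyllene	humulyl
(E)-β-caryophyllene	humulyl
α-humulene	humulyl
(+)-valencene	germacradienyl
α-selinene	germacradienyl
β-selinene	germacradienyl
γ-selinene	germacradienyl
7-epi-α-selinene	germacradienyl
germacrene A	germacradienyl
germacrene D	germacradienyl
β-elemene	germacradienyl
γ-cadinene	germacradienyl
α-amorphene	germacradienyl
(+)-aromadendrene	germacradienyl
(Z,E)-α-farnesene	nerolidyl_bisabolyl
α-bergamotene	nerolidyl_bisabolyl
camphene	nerolidyl_bisabolyl
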