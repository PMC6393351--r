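compound,VvivSBTPS01,VvivMATPS01,VvivSBTPS02,VvivMATPS10,VvivSHTPS27,VvivMATPS27,VvivMATPS28
β-Elemene,6.2,5.5,,,,,
(E)-β-Caryophyllene,,,100.0,,69.1,63.7,
(E)-β-Farnesene,,,,100.0,,,
α-Humulene,5.3,7.4,,,,,
β-Selinene (a),,,,,22.9,24.2,
γ-Selinene,6.3,,,,,,
Germacrene D,,,,,2.7,3.7,56.4
β-Selinene (b),16.4,15.1,,,,,
α-Selinene,38.1,49.1,,,,,
Camphene,,,,,,,12.1
γ-Cadinene,,,,,1.1,1.6,17.6
α-Amorphene,,,,,,,13.9
Germacrene A,23.6,20.0,,,0.9,1.4,
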