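# Fragment-library compound registry.
# Formulas are those reported in the HRMS characterization lines ([M+H]+ ion
# formulas) or derived from the named structure; exactly one of
# ion_formula / neutral_formula / heavy_atoms is given per row. Compounds
# without a published formula or structure assignment are omitted.
compound_id,name,ion_formula,neutral_formula,heavy_atoms
1,3-aminopyridin-2-one,,C5H6N2O,
2,3-amino-5-(1-methyl-1H-pyrazol-4-yl)pyridin-2(1H)-one,C9H11N4O,,
3,amrinone / 3-amino-5-(pyridin-4-yl)pyridin-2(1H)-one,,C10H9N3O,
5,6-methoxy-3-4'-bipyridin-5-amine,C11H12N3O,,
9,3-amino-5-phenyl-pyridin-2-one,C11H11N2O,,
10,3-amino-5-(pyrimidin-5-yl)pyridin-2(1H)-one,C9H9N4O,,
13,milrinone,,C12H9N3O,
15,3-amino-6-methyl-5-(pyridin-4-yl)pyridin-2-one,,C11H11N3O,
16,N-(2-oxo-5-(pyridin-4-yl)-1.2-dihydropyridin-3-yl)benzamide,C17H14N3O2,,
17,3-methoxy-N-(2-oxo-5-(pyridin-4-yl)-1.2-dihydropyridin-3-yl)benzamide,C18H16N3O3,,
18,3.5-dimethoxy-N-(2-oxo-5-(pyridin-4-yl)-1.2-dihydropyridin-3-yl)benzamide,C19H18N3O4,,
19,3-fluoro-N-(2-oxo-5-(pyridin-4-yl)-1.2-dihydropyridin-3-yl)benzamide,C17H13N3O2F,,
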