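# HRMS characterization lines: [M+H]+ ion formula with the calculated m/z
# as printed and the observed (found) m/z. Labels int-* are synthesis
# intermediates. The calc_mz for compound 16 follows a different electron
# convention in the source (see package vignette); cpd10's found value is a
# known transcription artifact in the source.
label,ion_formula,calc_mz,found_mz
cpd2,C9H11N4O,191.0927,191.0932
cpd5,C11H12N3O,202.0975,202.0986
int-2-methoxy-5-phenylpyridin-3-amine,C12H13N2O,201.1022,201.1030
cpd9,C11H11N2O,187.0866,187.0877
int-2-methoxy-5-(pyrimidin-5-yl)pyridin-3-amine,C10H11N4O,203.0927,203.0929
cpd10,C9H9N4O,189.0771,189.0711
cpd16,C17H14N3O2,292.1086,292.1075
cpd17,C18H16N3O3,322.1186,322.1182
cpd18,C19H18N3O4,352.1292,352.1291
cpd19,C17H13N3O2F,310.0986,310.0984
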