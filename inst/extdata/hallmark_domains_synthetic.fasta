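>rts88_v_gamma_synthetic
SSNLEGGTKSVTRPTGSSAVITCYLSTSGYNYLHWYQFFPGNRAERLIYDDSKSGKPKRFSGSKSGNTASLTISGLQAEIEADYFSASSELTAYYCALWEAQQYNSGWRKEFGSGTKLIVTP
>sc19_v_delta_synthetic
AQKVPQAQSSVSMPVRKVVTLNCLYEDRWSSGVLFWYVQYPNQGLQFLLRSEVPDGYNVSRSNTEDFPLRLELASPSQTSVYLTADSATYFCALDERDKSYTRWDRYDWAYLTNDGYWYDNYYRTRQMVWGTGTKLVFGE
>cd1d_g_alpha1_synthetic
AEVPDRLFPERCLQFSSMANSSWTRTDGLAWLGELQEHSWSNDSDTVRSLRSLLFGPYLQENQRHLAMDRMTQAELDIQELMVRYNHTEAFS
>cd1d_g_alpha2_synthetic
TELHVSWTAADMAAIGFQLKDASVMESQAWLQDLQDHQWDTVLDHISGFVSFQAKTETDIAFRIELRDWAKTSGIAELMRRYTLGPAGLQRLA
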