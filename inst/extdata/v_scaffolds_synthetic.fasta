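>V-GAMMA_scaffold_synthetic
SSNLEGGTKSVTRPTGSSAVITCDLSTSGDVGSSNYIQLHWYQQFPGKRAELLIYDVSKRPSGVPNRFSGSKSGNTASLTISGLQAEDEADYFSASSELTAYYCALWEAQQLGKKIEFGSGTKLIVTP
>V-DELTA_scaffold_synthetic
AQKVTQAQSSVSMPVRKAVTLNCLYEDRGSTYWYSSGVLFWYVQYPNQGLQLLLKSEATKQGSGVPDGYNVSRSNTEDFPLRLELASPSQTSVYLTADSATYFCALGERDKLTSQMVWGTGTKLVFGE
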