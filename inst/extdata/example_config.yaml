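seed: 1
threshold_ppm: 0.6
min_dwell: 1
variants:
  - name: synth-conformational
    mutations: A34F,V39L
    probe_residue: W43e
    reporter_residue: T17
    shifts: conf_shifts.tsv
    rates: conf_rates.tsv
    titration: conf_titration.tsv
    chemical: conf_chemical.csv
    thermal: conf_thermal.csv
    dihedrals: conf_dihedrals.tsv
  - name: synth-dimer-only
    mutations: A34F
    probe_residue: W43e
    reporter_residue: T17
    shifts: dimer_shifts.tsv
    rates: dimer_rates.tsv
    titration: dimer_titration.tsv
    chemical: dimer_chemical.csv
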