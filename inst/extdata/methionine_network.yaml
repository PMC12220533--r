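# Methionine-cycle network and synthetic study conditions.
# Pools: met, sam, sah, hcys, cyst (+ akb under the deuterated tracer);
# boundary pools medium_met / medium_hcys; protein-bound methionine sink.
# Free fluxes per condition (fmol/cell/h); dependent fluxes derived by
# steady-state balance. Concentrations in uM, times in minutes.
experiments:
  - cell_line: syn_tert
    condition: met_plus
    free_fluxes: {MTR: 0.26, CYSTS: 0.02, HCYS_release: 0.05,
                  AHCY_rev: 0.05, PROTSYN: 2.30, MET_release: 27}
    pools_uM: {met: 500, sam: 60, sah: 1.5, hcys: 1, cyst: 5}
    mean_diameter_um: 15.6
    doubling_time_h: 24
    cell_count_final: 317000
    baseline_medium_uM: {met: 100, hcys: 0}
  - cell_line: syn_ras
    condition: met_plus
    free_fluxes: {MTR: 0.43, CYSTS: 0.03, HCYS_release: 0.09,
                  AHCY_rev: 0.08, PROTSYN: 2.50, MET_release: 30}
    pools_uM: {met: 450, sam: 100, sah: 2.5, hcys: 1, cyst: 5}
    mean_diameter_um: 15.6
    doubling_time_h: 22
    cell_count_final: 252000
    baseline_medium_uM: {met: 100, hcys: 0}
  - cell_line: syn_tert
    condition: met_minus_hcys_plus
    free_fluxes: {MAT: 0.022, AHCY_rev: 1.2, CYSTS: 0.02,
                  HCYS_release: 0.10, PROTSYN: 1.84, MET_release: 0.02}
    pools_uM: {met: 5, sam: 12, sah: 6, hcys: 100, cyst: 8, akb: 2}
    mean_diameter_um: 15.6
    doubling_time_h: 30
    cell_count_final: 380000
    baseline_medium_uM: {met: 0, hcys: 100}
  - cell_line: syn_ras
    condition: met_minus_hcys_plus
    free_fluxes: {MAT: 0.012, AHCY_rev: 1.5, CYSTS: 0.015,
                  HCYS_release: 0.08, PROTSYN: 0.92, MET_release: 0.01}
    pools_uM: {met: 4, sam: 8, sah: 5, hcys: 110, cyst: 8, akb: 2}
    mean_diameter_um: 15.6
    doubling_time_h: 60
    cell_count_final: 314000
    baseline_medium_uM: {met: 0, hcys: 100}
fit_options:
  pools: free
  multistart: 10
  alpha: 0.05
  hf_floor: 0.02
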