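{
  "_comment": "Reporter-array geometries in 0-based half-open bp coordinates. The source constructs' exact segment lengths are not published; these defaults use a beta-globin-mini-gene-like scale (exons ~200-300 bp, introns 300 bp, MS2 region sized for 18 stem-loop repeats) and are fully overridable. E3 and E6 share the MS2-region length and per-intron geometry.",
  "E3": {
    "name": "E3",
    "length_bp": 3200,
    "exons": [[0, 200], [500, 700], [1000, 1300]],
    "introns": [[200, 500], [700, 1000]],
    "ms2_region": [1500, 2700],
    "n_ms2_repeats": 18,
    "exon_probe": [0, 200],
    "intron_probe_indices": [1, 2],
    "n_copies": 20
  },
  "E6": {
    "name": "E6",
    "length_bp": 4700,
    "exons": [[0, 200], [500, 700], [1000, 1200], [1500, 1700], [2000, 2200], [2500, 2800]],
    "introns": [[200, 500], [700, 1000], [1200, 1500], [1700, 2000], [2200, 2500]],
    "ms2_region": [3000, 4200],
    "n_ms2_repeats": 18,
    "exon_probe": [0, 200],
    "intron_probe_indices": [1, 2, 3, 4, 5],
    "n_copies": 20
  }
}
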