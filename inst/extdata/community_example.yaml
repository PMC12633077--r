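# Synthetic 16S-like community (no real accession behind it): five genera
# on the simplex, one oscillating with peak at ZT19. Dirichlet
# concentration sets compositional overdispersion; library sizes are
# lognormal around 20,000 reads.
period: 24
timepoints: [2, 6, 10, 14, 18, 22]
n_per_cell: [3, 4, 5, 6]
groups: [WT, KO]
concentration: 200
lib_median: 20000
lib_sdlog: 0.25
taxa:
  - taxon_id: Bacteroides
    lineage: "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides"
    baseline: 0.40
    amplitude: 0.10
    acrophase_h: 19
  - taxon_id: Blautia
    lineage: "Bacteria;Bacillota;Clostridia;Eubacteriales;Lachnospiraceae;Blautia"
    baseline: 0.25
  - taxon_id: Roseburia
    lineage: "Bacteria;Bacillota;Clostridia;Eubacteriales;Lachnospiraceae;Roseburia"
    baseline: 0.20
  - taxon_id: Akkermansia
    lineage: "Bacteria;Verrucomicrobiota;Verrucomicrobiae;Verrucomicrobiales;Akkermansiaceae;Akkermansia"
    baseline: 0.10
  - taxon_id: Escherichia
    lineage: "Bacteria;Pseudomonadota;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia"
    baseline: 0.05
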