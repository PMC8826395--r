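# hgtrace

Quantitative evidence chains for horizontal gene transfer (HGT) claims, in
R. The package is aimed at molecular evolution researchers who have a gene
tree that contradicts the species tree — the motivating case is the animal
peptidylarginine deiminase (PADI) family, whose closest relatives are
cyanobacterial — and who need more than topology to argue transfer against
the competing explanations (massive independent loss, or endosymbiotic gene
transfer through the proto-mitochondrion).

Four independent lines of evidence are implemented, plus the seeded
simulators that let every stage run end to end with known ground truth and
no downloads:

1. **Accumulated genetic divergence (AGD).** For a protein with homologs in
   a reference taxon, a bridge taxon and a distal taxon, with bit-score
   density `D(q,t) = bits(q,t) / bits(q,q)`,

   ```
   AGD = D(ref, bridge) − D(ref, distal)
   ```

   Vertically inherited proteins accumulate large AGD over the
   host–bacterium timescale; a transferred gene shows AGD near zero. A
   candidate is tested against control panels (ribosomal / EGT-candidate /
   mitochondrially encoded; Shapiro–Wilk normality, then a one-tailed
   z-score test).
2. **K-mer signature scan.** L1-normalized 4-mer spectra in 1 kb / 500 bp
   sliding windows, scored by deviation from the genome average, with
   robust-z flagging and interval merging — the standard check that a
   suspect gene does not sit on a compositionally alien (transferred or
   misattributed) segment.
3. **Synapomorphy typing.** Residue-level classification of PADI-like
   sequences into the three-domain cyanobacterial/animal type ("Ai") versus
   the two-domain actinobacterial/fungal type ("Bi"), from diagnostic
   states at human-PADI2-numbered positions (calcium switch D389 vs G,
   calcium-site-6 D125/E131 vs N/D, triple-His 300–302), with a
   per-group consensus report.
4. **Strict-clock root dating.** Penalized weighted least squares on a fixed
   rooted topology with normal fossil calibrations (the six calibrations of
   the motivating analysis ship as `default_calibrations()`), with a
   residual-bootstrap interval on the root age.

## Worked example

The numbered scripts under `analysis/` run the whole chain on simulated
data (`Rscript analysis/01_simulate_data.R`, then `02`–`06`), writing tables
under `results/`. The core AGD loop, by hand:

```r
library(hgtrace)

# species tree: reference-bridge split 700 Ma, distal lineage 2700 Ma
st <- agd_species_tree(root_age = 2700, split_age = 700, rate = 2.2e-4)
triple <- list(label = "fam", reference_id = "reference",
               bridge_id = "bridge", distal_id = "distal")

# vertical control panel, 26 families of 300 aa
vertical <- sapply(1:26, function(i) {
  fam <- simulate_family(st, scenario("vertical"), 300, seed = 1000 + i)
  compute_agd(triple, fam$sequences)$agd
})
pan <- panel_summary(vertical, "vertical_ribosomal")
print(pan)
#> AGD panel (vertical_ribosomal): n = 26, mean = 0.5073, sd = 0.04199
#> Shapiro-Wilk: W = 0.9543, p = 0.2922 (normality retained)

# one family transferred from the distal lineage at 750 Ma
fam <- simulate_family(st, scenario("hgt", donor = "distal",
                                    recipient = c("reference", "bridge"),
                                    time_ma = 750), 300, seed = 2001)
agd <- compute_agd(triple, fam$sequences)
print(z_outlier_test(agd$agd, pan, tail = "lower"))
#> z outlier test (lower tail): z = -11.71, p = 5.805e-32 -> reject at alpha = 0.05
```

The vertical panel sits at AGD ≈ 0.51 (the simulated analogue of the
published ribosomal panel mean of 0.70); the transferred family collapses to
AGD ≈ 0.016 and is rejected as a low outlier — the signature pattern of the
published PADI value of 0.07 against that panel. On the composition side,
`analysis/03_kmer_scan.R` flags one merged interval, `[47000, 52500)`,
covering 100% of the true 5 kb island inserted at `[47500, 52500)`; on the
dating side, `analysis/05_clock_dating.R` recovers a root age of 931 Ma
(95% bootstrap interval 822–1043) for a tree simulated with a 900 Ma root
and 10% branch-length noise.

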