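# gmycbar

Species delimitation on ultrametric gene trees with the single-threshold
general mixed Yule coalescent (GMYC) model, plus the character-based DNA
barcoding layer needed to assign degraded query sequences (e.g. a museum
holotype) to the delimited species.

The package is aimed at molecular systematists with a clock-like tree
over many individuals of an unknown number of species — the typical
output of single-locus barcoding of a radiation — who want to (1) test
whether the tree's branching pattern switches from between-species
diversification to within-species coalescence, (2) extract the implied
putative-species partition with confidence sets, and (3) diagnose and
classify short barcode fragments against those species, including
ancient-DNA quality control.

## The model

Every internode interval of the tree, with waiting time `x_i` and
lineage count `n_i`, contributes `log b_i − b_i x_i` to the
log-likelihood. The null model is a single coalescing population,

    b_i = λ [n_i(n_i−1)]^p ,

while the GMYC model switches at a threshold age `T`: branches crossing
`|T|` define entities, and each interval mixes a pure-birth
(diversification) term over the species-level lineages `n^s_i` with a
coalescent term over each entity's lineages `n_{j,i}`,

    B_i = λ1 (n^s_i)^{p1} + λ2 Σ_j [n_{j,i}(n_{j,i}−1)]^{p2} .

`T` is profiled over midpoints between distinct node ages; the maximum
likelihood threshold is compared to the null by a likelihood-ratio test
with 3 degrees of freedom (5 vs 2 free parameters), and all thresholds
within 2 log-likelihood units of the optimum form the confidence set on
the entity count and on `T`. Thresholds are reported as negative ages
(present = 0), usually after rescaling the root depth to 1.

Downstream, the partition feeds a character-based barcoding layer: pure
diagnostic sites (fixed in one entity, absent from all others) are
extracted per entity over a reference-anchored fragment, and query
sequences are classified by matched-rule counts. A small ancient-DNA
toolkit calls PCR-stratified clone consensus sequences and profiles
damage (the type-2 C→T/G→A deamination fraction) for authentication.

## Worked example

```r
library(gmycbar)

# simulate a radiation with known truth: 10 species, 4 samples each,
# within-species genealogies 20x shallower than their stems
sim <- sim_gmyc_tree(sim_config(n_species = 10, m = 4, s = 20,
                                nu = 0.005, seed = 12))
fit <- fit_gmyc(sim$tree)
fit
#> single-threshold GMYC fit
#>   logL (GMYC) = 204.8681, logL (null) = 175.8817
#>   LRT: 2dL = 57.9727, df = 3, p = 1.593e-12
#>   ML threshold T = -0.068126
#>   entities: 10 (0 singletons); K confidence set [10, 10]
#>   threshold confidence range [-0.068126, -0.068126]

glance(fit)      # one-row summary (threshold, K, logL, LRT, CI ranges)
tidy(fit)        # per-threshold profile (threshold, logL, K, rates)
fit$partition    # tibble: label, entity, kind (cluster/singleton)
autoplot(fit)                    # LTT with threshold and CI band
autoplot(fit, type = "profile")  # threshold log-likelihood profile
```

The fitted threshold (−0.068 on this tree) sits between the deepest
within-species genealogy and the shallowest species stem, so all 10 true
species are recovered as entities; the LRT rejects uniform branching
decisively. On a real chronogram read with `read_newick()` you would
typically `rescale_root(tree, 1)` first so the reported threshold is a
fraction of the root depth.

The barcode layer follows the same partition:

```r
aln   <- sim_sequences(sim$tree, "HKY", kappa = 3, L_seq = 85, rate = 2,
                       seed = 13)
rules <- find_diagnostics(aln, sim$partition)
classify_query(aln$sequence[1], rules)
#> barcode classification: 4 (margin 5, 100% of best entity's rules matched)
```

A thin command-line wrapper over these functions lives at
`inst/cli/gmycbar.R` (subcommands `gmyc-fit`, `simulate`, `diagnose`,
`classify`, `clone-consensus`, `damage-report`, ...).

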