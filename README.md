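# ecoassembly

Which ecological processes assemble a soil microbial community —
deterministic environmental filtering, dispersal, or drift?
`ecoassembly` answers this question per pair of samples with the
two-step phylogenetic null-model framework used in microbial community
ecology, and provides the full inference stack around it that a
plot-scale soil survey needs (for example, a replanted riparian strip
sampled for bacteria and fungi under different planting treatments).

## The core method

**Step 1 (selection).** For each pair of samples the between-community
mean nearest taxon distance

βMNTD(j,k) = ½ [ Σᵢ∈ⱼ fᵢⱼ · minᵢ′∈ₖ d(i,i′) + Σᵢ∈ₖ fᵢₖ · minᵢ′∈ⱼ d(i,i′) ]

(f relative abundance, d patristic distance) is compared to a null in
which tip labels are shuffled across all taxa; the z-score is the beta
nearest taxon index, βNTI. βNTI < −2 indicates homogeneous selection,
βNTI > +2 heterogeneous selection.

**Step 2 (dispersal vs drift).** Unresolved pairs are classified by the
Raup–Crick metric on Bray–Curtis dissimilarity (RC_Bray ∈ [−1, +1])
against an individual-based null that reassembles each community from
the regional pool (richness by occurrence frequency, reads by regional
relative abundance). RC > +0.95 is dispersal limitation, RC < −0.95
homogenizing dispersal, otherwise the pair is undominated.

Around this core the package implements depth filtering, rarefaction,
cumulative sum scaling, collinearity pruning of soil chemistry, Shannon
diversity, Bray–Curtis/PCoA, PERMANOVA, Mantel distance-decay,
Procrustes congruence tests, distance-based forward selection (DistLM),
dbMEM environment/space variance partitioning, IndVal indicator
analysis, and a metacommunity simulator that generates communities
assembled under each of the five processes for validation. See the
methods vignette (`vignettes/community-assembly.Rmd`) for the models,
parameter choices and simulator design.

## Worked example

Simulate a metacommunity assembled under homogeneous selection,
preprocess it the way a real survey would be, and ask the classifier
which process dominates:

```r
library(ecoassembly)

ds <- assemble_communities(
  scenario_config("homogeneous_selection", n_samples = 32, seed = 1))

al   <- align_inputs(ds$table, ds$tree, ds$frame)
al   <- align_inputs(filter_low_depth(al$table, 1000), al$tree, al$frame)
rare <- rarefy(al$table, min(rowSums(al$table)), seed = 1)

planted <- tab_subset(rare, which(al$frame$plot_type != "grass"))
planted <- tab_subset(planted, j = which(colSums(planted) > 0))
planted
#> comm_table [rarefied]: 21 samples x 657 taxa

pairs <- assembly_processes(planted, al$tree, n_null = 999, seed = 1)
head(as.data.frame(pairs), 3)
#>   sample_i sample_j beta_mntd_obs      bnti    rc_bray               process
#> 1      S02      S03     0.6199426 -2.650116         NA homogeneous_selection
#> 2      S02      S04     0.6394337 -1.443074 0.02702703           undominated
#> 3      S02      S05     0.8427591 -1.966307 0.99599600  dispersal_limitation

summarize_processes(pairs)
#>                   process   n   percent
#> 1   homogeneous_selection 200 95.238095
#> 2 heterogeneous_selection   0  0.000000
#> 3    dispersal_limitation   3  1.428571
#> 4  homogenizing_dispersal   0  0.000000
#> 5             undominated   7  3.333333
```

Reading the output: pair S02–S03 has βNTI = −2.65, below the −2
threshold, so its turnover is attributed to consistent environmental
filtering (RC_Bray is not needed and stays `NA`); pair S02–S04 is inside
both thresholds — undominated; and 95.2% of all 210 pairs are correctly
attributed to homogeneous selection, the process the simulator used.
`run_pipeline()` executes the same steps (plus diversity, PERMANOVA,
distance-decay, variance partitioning) end to end and writes TSV tables
and a reproducibility manifest.

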