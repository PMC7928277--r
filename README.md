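# ethnomineR

Association mining and citation statistics for ethnobotanical prescription
surveys.

An ethnobotanical pharmacy survey produces a transaction corpus: every
purchased prescription is a set of standardized medicinal materials. This
package implements the quantitative half of such a study for analysts of
traditional-medicine formula data:

* **Relative frequency of citation.** RFC = FC/N, with FC the number of
  prescriptions citing a material and N the corpus size in prescriptions;
  materials with RFC ≥ 0.2 are the *frequently used* set.
* **Categorical profiling** of the frequent materials — taxonomy, plant
  part, thermal property, flavor, curated pharmacology tags — under explicit
  counting conventions (per material for single-valued variables, per token
  for multi-valued ones).
* **Drug-pair mining.** Exact pairwise co-occurrence support, high-frequency
  pairs above a count threshold (strict `>` by default), and directional
  association rules with confidence support(A,B)/FC(A); confidence-1 rules
  (A is never prescribed without B) are decided by integer equality.
* **Co-prescription network inference.** A weighted undirected graph over
  the frequent materials with support-thresholded edges, exported as GraphML
  and TSV, plus a deterministic core-material ranking (citation count,
  weighted-degree tie-break).
* **A seeded synthetic corpus generator** (independent Bernoulli marginals,
  mixture-coupled pair boosts, acyclic deterministic implications) so every
  stage is testable when the underlying survey data are not distributable.

The packaged reference fixture transcribes the 19 frequently used materials
of a survey of galactagogue (lactation-promoting) prescriptions from
traditional Chinese medicine pharmacies — 90 prescriptions, 81 materials —
with their printed RFC values, properties, flavors and pharmacology tags.

## Worked example

```r
library(ethnomineR)

dir <- system.file("extdata", package = "ethnomineR")
corpus <- readCorpus(dir,
                     registry      = "galactagogue_registry.csv",
                     prescriptions = "toy_prescriptions.csv",
                     synonyms      = "toy_synonyms.csv")

head(computeRFC(corpus), 5)
#>             material_id fc n rfc rfc_display
#> 1     angelica_sinensis  4 5 0.8         0.8
#> 2  tetrapanax_papyrifer  4 5 0.8         0.8
#> 3 glycyrrhiza_uralensis  2 5 0.4         0.4
#> 4  hedysarum_polybotrys  2 5 0.4         0.4
#> 5       lycium_chinense  1 5 0.2         0.2
```

Four of five toy prescriptions cite *Angelica sinensis* (RFC 0.8); RFC 0.2
is the conventional inclusive boundary for the frequent set.

```r
pairs <- countPairs(corpus)
head(pairs[, c("material_a", "material_b", "support",
               "conf_a_to_b", "conf_b_to_a")], 3)
#>             material_a            material_b support conf_a_to_b conf_b_to_a
#> 1    angelica_sinensis  tetrapanax_papyrifer       3        0.75        0.75
#> 2    angelica_sinensis glycyrrhiza_uralensis       2        0.50        1.00
#> 3 hedysarum_polybotrys  tetrapanax_papyrifer       2        1.00        0.50
```

`conf_b_to_a = 1` in row 2 says every toy prescription containing
*Glycyrrhiza uralensis* also contains *A. sinensis* — a confidence-1
association rule.

```r
net <- buildNetwork(pairs, computeRFC(corpus),
                    edgeThreshold = 1, nodeCutoff = 0.2)
coreRanking(net, k = 3)
#> [1] "angelica_sinensis"    "tetrapanax_papyrifer" "glycyrrhiza_uralensis"
```

Profiles of the packaged 19-material registry reproduce the survey's
published summary numbers:

```r
reg <- galactagogueRegistry()
profileCategorical(reg, "tcm_property", "per_material")[, c("category", "count", "percent_display")]
#>   category count percent_display
#> 1     warm    11              58
#> 2    plain     5              26
#> 3     cold     2              11
#> 4     cool     1               5
```

`runPipeline(pipelineConfig(...))` drives corpus loading (or generation),
RFC, profiles, pairs, rules and network end to end, writing CSV tables, a
GraphML network, a Markdown report and a JSON run manifest. A thin
command-line front end with `analyze` and `simulate` subcommands lives at
`system.file("scripts", "prescription-mine.R", package = "ethnomineR")`.

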