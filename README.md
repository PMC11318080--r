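# APNet

Attribute-guided prototype networks for few-shot molecular property
prediction in R.

## The problem

Most assays that matter in drug discovery — a toxicity endpoint, a side
effect, activity against a new target — come with only a handful of
labelled molecules. APNet is for computational chemists and method
developers who want to predict such a *previously unseen* binary property
from K labelled examples per class, by meta-learning across many related
property tasks.

The model is a prototypical network over molecular graphs whose
representations are gated by human-defined molecular attributes. For a
molecule with node embeddings $G = \{g_j\}_{j=1}^N$ (from a five-layer
graph attention network by default; GCN, GIN and GraphSAGE are drop-in
variants) and attribute vector $a$ (any of 14 fingerprint families —
ECFP/FCFP, RDKit path, hashed atom-pair/torsion, MACCS, Avalon — reduced
to 100 dimensions by PCA, combined by addition or concatenation, or a
precomputed deep embedding):

- local gate: $g'_j = \sigma(f_{local}([g_j; a])) \otimes g_j$
- pooling: $\bar g = \tfrac1N \sum_j g'_j$
- global gate: $z' = \sigma(f_{global}([\bar g; a])) \otimes \bar g$

Episodes are 2-way K-shot tasks. Each class prototype is a
distance-weighted sum of its support representations,
$p = \sum_i a_i z'_i$ with $a_i \propto 1/\sum_j \lVert z'_i - z'_j
\rVert_2$, so outlying supports count less. Queries are classified by a
two-way softmax over dot-product similarities to the two prototypes, and
training minimizes the episodic cross-entropy with Adam. Evaluation on
unseen tasks repeats support/query sampling over independently seeded
runs and reports ROC-AUC, F1 and PR-AUC. An attribute screening harness
ranks attributes and classifies attribute pairs as mutual promotion /
one-sided promotion / mutual inhibition (R1/R2/R3).

All chemistry (SMILES parsing, fingerprints, substructure matching) is
delegated to RDKit through a bundled Python helper; the model, trainer
and evaluation protocol are implemented in R. A deterministic synthetic
benchmark generator (motif-defined tasks over a generated molecule
library) makes the whole pipeline testable without external data.

## Worked example

Generate a 600-molecule benchmark with 12 motif-defined tasks (9 for
meta-training, 3 unseen for meta-testing), train with ECFP4 attributes,
and evaluate on the unseen tasks:

```r
library(APNet)

bench <- makeBenchmark(synthSpec(nMolecules = 600, seed = 7))
bench$molSet
#> MoleculeSet: 600 molecules, 12 tasks
#>   graphs: featurized

attrs <- computeAttributes(bench$molSet, "ECFP4")
attrs
#> AttributeSet 'ecfp4' (agg=none): 600 x 100

cfg <- trainConfig(K = 10, q = 32, episodes = 200, evalEvery = 50,
                   lr = 5e-4, seed = 7)
model <- metaTrain(bench$molSet, attrs, bench$split,
                   encoderConfig("GAT"), cfg)
model
#> APNModel: GAT encoder, 5 layers, d^g = 100
#>   attribute dim: 100
#>   trained: 200 episodes, best val ROC-AUC 0.9453

report <- metaEvaluate(model, bench$molSet, attrs, bench$split, runs = 10)
report
#> EvalReport: K = 10 , q = 32 , 10 runs per task
#>        task runs rocAuc rocAucSd     f1    f1Sd  prAuc prAucSd
#>       amide   10 0.8039  0.06211 0.6730 0.11030 0.8085 0.07684
#>        iodo   10 0.6484  0.10473 0.6489 0.07157 0.6658 0.11051
#>  pyrimidine   10 0.7867  0.08105 0.6924 0.11766 0.7947 0.06830
#>   overall: ROC-AUC 0.7464 (0.1079), F1 0.6714 (0.0999), PR-AUC 0.7563 (0.1065)
```

The validation score (0.95) is ROC-AUC on held-out molecules of the
*training* tasks; the evaluation table shows transfer to the three unseen
motif tasks — iodo, amide and pyrimidine were never seen during training,
so every bit of performance above 0.5 comes from support-set prototypes
in the learned representation. Attribute pairs can be classified with the
published score convention:

```r
classifyRelationship(0.8352, 0.8254, 0.8221)
#> $relation
#> [1] "R1"
#> $heatmap
#> [1] 1
```

A thin command-line wrapper over the same functions lives in
`inst/scripts/apn.R` (`synth`, `attrs`, `train`, `eval`, `screen`
subcommands).

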