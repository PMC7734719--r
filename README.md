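# kgwalc

Interpretable node classification on knowledge graphs by mining
**discriminative wildcard walks**.

A knowledge graph stores domain knowledge as (subject, predicate, object)
triples. Given entities with class labels — researchers and their
affiliations, molecules and their carcinogenicity, rock units and their
genesis — `kgwalc` finds walk patterns

```
root -> * -> ... -> * -> x        (written as the tuple w = (x, l))
```

whose presence within `l` hops of an entity maximizes the information
gain

```
IG(D, w) = H(D) − (|Df|/|D|)·H(Df) − (|Dnf|/|D|)·H(Dnf)
```

where `Df` / `Dnf` split the dataset by walk presence and `H` is Shannon
entropy in bits. Every triple is first converted to
`subject -> predicate-vertex -> object` (a fresh predicate vertex per
triple), and each entity gets depth-indexed neighborhood label sets that
make walk containment a constant-time membership test. On top of the
miner sit three classifiers:

* **Decision tree** — walks mined recursively; every prediction comes
  with its root-to-leaf path of walk tests (DOT export included).
* **Forest** — bootstrap + per-node candidate sampling, with global walk
  importances (position-weighted counts).
* **Feature transform** — one pass keeps the top-K walks and emits
  binary presence matrices (MTX + TSV) for any downstream classifier.

The audience is anyone who needs *transparent* models on RDF data —
e.g. biomedical informatics, where a black-box embedding is not an
acceptable justification for a decision.

## Worked example

The bundled toy graph is a three-class, imbalanced problem: 8 entities of
class A each link to shared nodes "1".."5", 2 entities of class B link to
node "6", 2 entities of class C link to node "7".

```r
library(kgwalc)
fx <- makeImbalancedToyGraph()
nb <- extractNeighborhoods(fx$graph, entities(fx$data), 1)

labelEntropy(classLabels(fx$data))
#> [1] 1.251629

mineWalks(fx$data, nb, n = 7)
#>   end_label depth   ig_bits n_found
#> 1         1     1 0.9182958       8
#> 2         2     1 0.9182958       8
#> 3         3     1 0.9182958       8
#> 4         4     1 0.9182958       8
#> 5         5     1 0.9182958       8
#> 6         6     1 0.6500224       2
#> 7         7     1 0.6500224       2
```

The prior entropy of the 8/2/2 labels is 1.2516 bits. Every
majority-class walk gains 0.9183 bits, strictly more than the 0.6500 bits
of the two minority separators — so a single-pass top-K ranking must keep
**six** walks before the classes become linearly separable, while the
decision tree, which re-mines inside each partition, needs only **two**:

```r
tree <- buildWalkTree(fx$data, nb, maxWalkDepth = 1)
cat(serializeWalkTree(tree), sep = "\n")
#> split walk=(1, 1) ig=0.918296 n=12
#>   found: leaf class=A n=8
#>   not_found: split walk=(6, 1) ig=1.000000 n=4
#>     found: leaf class=B n=2
#>     not_found: leaf class=C n=2

numInternalNodes(tree)
#> [1] 2

m5 <- featurize(mineTopK(fx$data, nb, K = 5), entities(fx$data), nb)
m6 <- featurize(mineTopK(fx$data, nb, K = 6), entities(fx$data), nb)
isLinearlySeparable(featureValues(m5), classLabels(fx$data))
#> [1] FALSE
isLinearlySeparable(featureValues(m6), classLabels(fx$data))
#> [1] TRUE
```

RDF pipelines run the same way from files — `readTriples()` (N-Triples /
Turtle subset), `convertToLabeledGraph()` with a label-leaking-predicate
exclusion list, `readEntityLabels()` — or from the shell:

```sh
kgwalc tree      --graph g.nt --labels train.tsv --depth 8 --max-tree-depth 5
kgwalc forest    --graph g.nt --labels train.tsv --depth 8 --n-trees 25 \
                 --vertex-sample 0.5 --bootstrap
kgwalc transform --graph g.nt --labels train.tsv --depth 8 --k 10000 \
                 --mode per_class
```

(`exec/kgwalc`; run it with `Rscript exec/kgwalc ...` if the installed
copy is not on your `PATH`.) Synthetic knowledge graphs with planted
discriminative walks — used throughout the test suite — come from
`plantedKGSpec()` / `makePlantedKG()`.

See `vignettes/walk-mining-methods.Rmd` for the model, the parameter
reference, and the design decisions.

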