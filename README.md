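# meristemNet

Network-based prediction of cell division and topology rewiring in the shoot
apical meristem (SAM) epidermis.

## What it does, and for whom

The epidermis of the plant shoot apical meristem changes its cell-to-cell
topology only through cell division. meristemNet is for developmental and
systems biologists who have per-time-point segmentation exports (cell
centroids, surface areas, perimeters, shared walls, and a manual lineage
between consecutive days) and want to model that process quantitatively. The
tissue is represented as a **cell-connectivity network** — nodes are cells,
edges join cells sharing a wall — under four edge weightings (unweighted,
inverse mean cell area, inverse shared wall, inverse centroid distance), and
two linear support-vector classifiers are trained on it:

1. **Division events.** Each central, non-peripheral cell is labeled +1
   (divides within 24 h) or −1, and classified from 50 per-cell topological
   features (17 per scenario, 11 weight-sensitive) and/or its surface area:
   `sign(w · x_z + b)`, with inverse-class-frequency weights in the hinge
   loss and plant-wise cross-validation for the regularization constant C.
2. **Post-division rewiring.** For each (dividing parent, neighbor) pair, the
   neighbor ends up adjacent to daughter A only — the daughter nearer the
   tissue center — (class 0), to daughter B only (class 1), or to both
   (class 2); a 3-class one-vs-rest linear SVM predicts the class from
   parent + (neighbor − parent) topological features and six biological pair
   features (areas, perimeters, shared wall, centroid distance).

Applied in sequence, the two models **propagate** an observed tissue graph
one day forward — each predicted divider is replaced by an adjacent daughter
pair, former neighbors reconnected per predicted class — and the result is
scored against the observed next-day topology by per-feature Pearson
correlations over co-non-dividing cells, against a random-propagation
baseline, and by per-division neighbor accuracy with a Kolmogorov–Smirnov
test.

Because no imaging dataset ships with the method, the package includes a
seeded **synthetic tissue simulator** (Lloyd-relaxed Voronoi tessellations
that grow, divide by shortest-wall placement, and emit exact lineage and
rewiring ground truth), so the whole pipeline is testable end to end.

## Worked example

```r
library(meristemNet)

# simulate a cohort of four plants (growing, dividing epidermal tissues)
params <- simParams(nCellsInit = 150, diskRadius = 50, steps = 3)
cohort <- simulateCohort(params, nPlants = 4, seed = 11)

# labeled datasets: division events per cell, rewiring classes per pair
divData  <- assembleDivisionDataset(cohort, featureSet = "topo+area")
pairData <- assemblePairDataset(cohort, featureSet = "topo+bio")

# plant-wise splits: one held-out test plant, leave-one-plant-out CV
splits <- makeSplits(sampleData(divData)$plant, nTestPlants = 1, seed = 11)

divFit  <- trainDivisionClassifier(divData, splits, cGrid = c(0.01, 0.1, 1, 10),
                                   featureSet = "topo+area")
pairFit <- trainPairClassifier(pairData, splits, cGrid = c(0.01, 0.1, 1, 10),
                               seed = 11, featureSet = "topo+bio")

# held-out evaluation
ev <- evaluateClassifier(divFit$model,
                         divData[, sampleData(divData)$plant %in% splits$testPlants])

# propagate the test plant one day forward and compare with the observation
ser  <- cohort[[splits$testPlants[1]]]
prop <- propagateTissue(tissueGraphs(ser)[[1]], divFit$model, pairFit$model,
                        seed = 11)
cmp  <- compareTopologies(prop, tissueGraphs(ser)[[2]], lineageMaps(ser)[[1]])
acc  <- localRewiringAccuracy(prop, tissueGraphs(ser)[[2]],
                              lineageMaps(ser)[[1]], seed = 11)
```

Output of this exact script:

```
division: validation balanced accuracy 0.759 +/- 0.007 (C = 1)
division: test balanced accuracy 0.773, AUC 0.832
rewiring: validation balanced accuracy 0.711 (chance = 0.333)
propagation: 95 co-non-dividing cells; top feature correlations:
              feature         r
             harmonic 0.9681927
            closeness 0.9670038
 currentFlowCloseness 0.9567538
rewiring accuracy per division: 73.7% (KS vs random: p = 2.1e-07)
```

Reading it: the division classifier recovers the planted size-and-centrality
division rule well above the 0.5 chance level on a plant it never saw; the
rewiring classifier more than doubles the 1/3 chance level; and the
propagated topology tracks the observed one closely for the flow- and
path-based centralities, with the per-division neighbor accuracy far above
random labeling.

Real segmentation exports enter through `readTissueGraph()` /
`readTissueGraphCSV()` (node-link JSON or a two-file CSV dialect) and
`readLineageMap()`; `runPipeline()` drives the whole sequence from a YAML
config and writes every artifact — feature tables with provenance sidecars,
model JSONs, per-feature correlation rankings, a resolved config — to an
output directory.

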