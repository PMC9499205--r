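# ramus3d

Surface- and voxel-based rigid registration on the mandibular ramus for
long-term 3D assessment of condylar remodelling after orthognathic surgery —
as a fully tested, ground-truthed simulation and analysis pipeline in R.

## The problem

After a bilateral sagittal split osteotomy, the mandibular condyle may
remodel or resorb over the following years. Measuring that change from pre-
and postoperative CBCT requires rigidly superimposing the two scans on an
anatomical reference structure assumed stable — the coronoid process plus
the ramal band between the mandibular notch and the posterior border — and
then quantifying, per anatomical region, the surface displacement and
volume change of the bone. Two registration families compete for the
superimposition: **surface-based** (iterative closest point, ICP, on the
reconstructed bone surfaces) and **voxel-based** (maximisation of
normalised mutual information, NMI, over the grey values inside the masked
region of interest),

&nbsp;&nbsp;&nbsp;&nbsp;NMI(F, M) = (H(F) + H(M)) / H(F, M),

estimated on a 32 × 32 joint histogram with partial-volume interpolation.
The ramus is partitioned by anatomical cutting planes derived from
cephalometric landmarks (Frankfurt plane, C-plane through the mandibular
notch, ramus / posterior / anterior / inferior ramus planes and their
equally spaced intermediates) into the condyle, the coronoid process and 20
ramal subregions. Accuracy is the per-region area-weighted mean absolute
surface distance after alignment; reliability between two observers is
summarised by the intraclass correlation ICC(1,1) (one-way random effects,
single measures, exact F-based 95 % CI),

&nbsp;&nbsp;&nbsp;&nbsp;ICC(1,1) = (MSB − MSW) / (MSB + (k − 1) MSW),

mean absolute differences (MAD ± SD), and per-region paired t-tests between
the two methods.

Because clinical CBCT cannot be redistributed, the package ships a
synthetic hemimandible phantom: a parametric implicit solid (ramal blade,
condylar head, coronoid process, gonial bulge) extracted by marching
tetrahedra, with every cephalometric landmark a unique, brute-force
verifiable extremum, CBCT-like two-level intensities, known rigid
displacements, parametric condylar/reference resorption, and simulated
observers. All experiments are pure functions of their seeds.

## Worked example

```r
library(ramus3d)

# a ground-truthed case: phantom, landmarks, planes, 22-region labelling
case <- generateRamus(seed = 3, volumeSpacing = 0.6)
disp <- randomRigidTransform(5, 10,
                             center = colMeans(vertices(case@preopMesh)),
                             seed = 42)
case <- buildPostop(case, disp,
                    resorptionSpec("condyle", 1.0, falloff = 3,
                                   affectedFraction = 0.7))

ref  <- buildReferenceStructure(case@preopMesh, case@landmarks, side = "R",
                                planes = case@planes,
                                volume = case@preopVolume)
init <- prealign(case@landmarks, applyTransform(case@landmarks, disp))

icp <- icpRegister(case@preopMesh, case@postopMesh, ref, init = init)
icp
#> RegistrationResult (surface): converged = TRUE, metric = 2.62506e-06, 2 iterations

aligned <- applyTransform(case@postopMesh, icp@transform)
d   <- surfaceDistances(case@preopMesh, aligned)
acc <- regionAccuracy(case@labeling, d, case@preopMesh)
round(acc[c("condyle", "coronoid", "R01", "whole")], 3)
#>  condyle coronoid      R01    whole
#>    0.818    0.000    0.000    0.190
```

The condyle shows the simulated resorption (mean absolute distance
0.82 mm), while the coronoid process and the reference band sit at the
sub-micron level — the pattern that distinguishes true remodelling from
registration error. A full cohort comparison (both engines, two simulated
observers, ICC/MAD/paired-t reports, explicit failure rows for
uninformative voxel ROIs) runs with:

```r
res <- runExperiment(experimentConfig(nRami = 20, seed = 1))
head(res$reliability); res$failures
```

A thin CLI over the same functions lives at `inst/scripts/ramus3d.R`
(subcommands `simulate`, `register`, `run-all`).

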