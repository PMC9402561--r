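# qmribids

Quantitative MRI (qMRI) estimates physical tissue parameters — relaxation
times T1, T2 and T2\*, proton density, magnetization transfer, the RF
transmit field B1+ — by fitting a biophysical signal model to a set of
images acquired while one acquisition parameter is systematically varied.
In BIDS such a set is an **entity-linked file collection**: a group of
NIfTI volumes sharing a suffix that names the acquisition scheme (e.g.
`MP2RAGE`, `VFA`, `MEGRE`, `TB1DAM`) and distinguished by linking entities
(`echo-`, `flip-`, `inv-`, `mt-`, `part-`) that *index* the varied
parameter; the parameter values themselves live in sidecar JSON metadata.

`qmribids` implements this convention as a working toolkit for R, aimed at
qMRI methods developers and anyone curating or checking qMRI datasets:

* **Schema registry** — a declarative, machine-readable description of all
  14 collection suffixes (8 anatomy, 6 field-map), their entity
  requirement levels, required metadata and derivable maps, plus the
  standardized map units (times in s, rates in 1/s, ratios in %,
  susceptibility in ppm, transmit field in relative % with 100 = nominal).
* **BIDS I/O** — filename parsing/building, sidecar resolution with the
  inheritance principle (nearest file wins), NIfTI volume I/O.
* **Validator** — filename-, collection- and metadata-level rules emitting
  machine-readable issues (`QV_*` codes, error/warning severities),
  including the metadata-level checks that directory/filename-level
  validators do not cover.
* **Signal models & fitters** — pure forward models and deterministic
  voxelwise inverses for VFA, inversion recovery, multi-echo T2/T2\*,
  MP2RAGE (exact affine steady state + lookup inversion of the UNI
  combination), MTR, MTsat, double-angle and actual-flip-angle B1+
  mapping.
* **Digital phantom** — a synthetic-dataset generator that forward-models
  every registered suffix on a geometric tissue phantom and writes a valid
  raw dataset (plus ground truth beside it), so fitters and validator can
  be exercised without scanner data.
* **Derivatives** — quantitative maps written with registry units,
  `BasedOn` input provenance, varying-parameter vectors and a generating
  software block; unit dialects are rejected, never silently converted.

## Core models

For a spoiled gradient echo at flip angle α and repetition time TR,

    S = M0 · sin(b1·α) · (1 − E1) / (1 − E1·cos(b1·α)),   E1 = exp(−TR/T1)

which the VFA fitter inverts by linearized least squares on
y = S/sin α vs x = S/tan α. Inversion recovery uses
S(TI) = a + b·exp(−TI/T1) with polarity restoration for magnitude data;
multi-echo data use weighted log-linear fits of S = M0·exp(−TE/tc).
MP2RAGE propagates the longitudinal magnetization through one
inversion–block–block cycle as a composition of affine maps, solves the
steady state exactly, and inverts the bias-free combination
UNI = Re(S1·S̄2)/(|S1|²+|S2|²) ∈ [−0.5, 0.5] by monotone lookup. B1+ maps
come from the double-angle identity S2/(2·S1) = cos(b1·α) or the
dual-TR AFI ratio r = (1 + n·cos α)/(n + cos α), n = TR2/TR1; MTsat uses
the rational small-angle steady state with closed-form inversion for
R1, the apparent amplitude A and the per-excitation saturation δ.

## Worked example

```r
library(qmribids)

root <- file.path(tempdir(), "demo-ds")
generateDataset(outRoot = root,
                protocols = defaultProtocols(c("MEGRE", "TB1DAM")))

issueSummary(validateDataset(root))
#> $n_errors
#> [1] 0
#> $n_warnings
#> [1] 0

colls <- groupCollections(root)
fc <- colls[[which(sapply(colls, collectionSuffix) == "MEGRE")]]
fc
#> FileCollection <MEGRE> sub-01
#>   folder: anat; members: 10; linking entities: {echo}

head(parameterTable(fc)[, c("file", "echo", "EchoTime")], 3)
#>                          file echo EchoTime
#> 1 sub-01_echo-01_MEGRE.nii.gz    1    0.006
#> 2 sub-01_echo-02_MEGRE.nii.gz    2    0.012
#> 3 sub-01_echo-03_MEGRE.nii.gz    3    0.018

res <- fitCollection(fc)
res$fit
#> FitResult with map(s): T2starmap [s], M0map [arbitrary]
#>   voxels fitted: 11536/32768

writeMap(res$maps$T2starmap, file.path(root, "derivatives", "qmribids"))
```

The fitted `T2starmap` is in seconds (the registry unit); the 11,536
fitted voxels are the phantom's three nested tissue spheres (the empty
background is masked as NaN). The written sidecar lists all ten echo
images under `BasedOn`, the ten `EchoTime` values as a vector, and
`MagneticFieldStrength` inherited from the raw data — everything needed
to interpret and reproduce the map.

A command-line wrapper is installed as `exec/qmribids`:

```sh
qmribids validate <root> [--json-report report.json] [--strict]
qmribids generate --out <dir> [--config cfg.yaml] [--seed 5]
qmribids fit --collection MEGRE --root <dir> [--out <dir>] [--b1 map.nii.gz]
```

Exit codes: 0 valid/success, 1 validation errors or fit failure, 2 usage
error.

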