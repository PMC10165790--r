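# BraceMorph

Quantitative 3D shape analysis for CAD-designed scoliosis braces.

In adolescent idiopathic scoliosis (AIS), the *initial in-brace correction*
(IBC) — the percentage reduction of the major-curve Cobb angle on the first
in-brace radiograph, `IBC = 100 (CA_pre − CA_inbrace) / CA_pre` — is a
strong predictor of brace-treatment success. When braces are designed from
3D torso scans, the scan and the virtual brace model carry shape
information that may relate to IBC. BraceMorph implements the measurement
pipeline that extracts this information and correlates it with IBC:

* **Torso/brace asymmetry index** — mirror the surface across its
  mid-sagittal plane, register the mirror back with iterative closest point
  (ICP), trim both to equal length, and report the volume of the Boolean
  symmetric difference divided by the torso volume, in percent.
* **Signed displacement field** — for every torso vertex, the distance to
  the closest point on the brace surface, positive where the brace presses
  into the torso (*pressure zone*) and negative where it leaves room
  (*expansion zone*); summarised as the peak positive/negative displacement
  in the 12 standard segments (anterior/posterior × left/right ×
  upper/mid/lower: ALU … PRL).
* **Cohort statistics** — IBC from Cobb angles, Spearman rank correlations
  (ρ) of shape features against IBC per Lenke curve type, with the
  conventional strength bins (|ρ| ≥ 0.90 very strong, 0.70–0.89 strong,
  0.50–0.69 moderate, 0.26–0.49 weak, ≤ 0.25 little if any).
* **Synthetic phantoms** — watertight scoliotic torso phantoms, derived
  braces with Gaussian pad/relief zones, and seeded cohorts with a known
  feature→IBC effect structure, so the whole pipeline is testable without
  patient data.

The geometric core (STL/PLY/OBJ mesh I/O, exact closest-point queries,
generalized winding numbers, voxel symmetric-difference volumes, slab
slicing with caps, point-to-point ICP) is implemented in the package with
Rcpp, and is exercised against analytic and brute-force oracles in the test
suite.

## Worked example

```r
library(BraceMorph)

# a scoliotic phantom: 15 mm lateral curve offset, 12 mm rib hump
torso <- generateTorso(torsoParams(lateralOffset = 15, humpAmplitude = 12))
asymmetryIndex(torso, icpConfig(seed = 1), voxelPitch = 2)
#> AsymmetryResult: 7.308 %
#>   inter-surface volume: 1396432.0 mm^3 / total volume 19108934.4 mm^3
#>   ICP: rms 4.7081 mm in 40 iterations; trim z [0.0, 500.0] mm; pitch 2.0 mm
```

The phantom deviates from its mirror image by 7.3 % of its volume — the
asymmetry index. A brace derived from this torso with a pressure pad in the
posterior-left midsegment and a relief zone in the anterior-right
midsegment:

```r
brace <- generateBrace(torso, list(padSpec("PLM", 8), padSpec("ARM", -6)))
field <- signedDisplacementField(torso, brace)
field
#> DisplacementField on 2306 vertices: 45.7% pressure (+), 43.1% expansion (-)
#>   range [-5.94, 7.88] mm
pk <- segmentPeaks(field, partitionSegments(torso))
peaksTable(pk)[c(4, 9), 1:3]
#>  segment peakPositive peakNegative
#>      ARM       0.0000      -5.9377
#>      PLM       7.8776       0.0000
```

The planted 8 mm pad and −6 mm relief are recovered in the right segments
to within a few percent (the small shortfall is the finite pad slope and
mesh resolution). Cohort-level:

```r
computeIBC(38.4, 32.2)        # pre-brace 38.4°, in-brace 32.2°
#> 16.14583                    # percent correction
classifyStrength(-0.85)
#> strong
rec <- generateCohort(cohortModel(seed = 1))      # 11 Lenke-1 + 14 Lenke-5
correlationTable(rec, lenkeType = 5, outcome = "ibcAP")
```

`runCohort(manifest, runConfig(outputDir = "out", seed = 1))` runs the full
per-patient chain from mesh files listed in a manifest CSV and writes the
study tables (characteristics summary, asymmetry correlations, and one
24-feature correlation table per Lenke group and radiographic view) plus a
run report. A thin CLI over these functions is in
`inst/scripts/bracemorph.R` (verbs `asymmetry`, `displace`, `patient`,
`cohort`, `simulate`).

Note one reporting convention: correlations for `peakNegative_*` features
are computed on the expansion **depth** (magnitude), so a negative ρ reads
"larger expansion zone, less correction".

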