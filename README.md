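# ProtSphere

Fuzzy spherically truncated multi-linear 3D protein descriptors.

## What this package is for

ProtSphere computes alignment-free numeric descriptors of protein 3D
structure for QSAR-style modelling (folding-rate regression, structural-class
discrimination, descriptor screening). Each protein is reduced to one point
per residue — the Cα atom (`CA`), the Cβ atom (`CB`, Cα for glycine), the
backbone amide-bond midpoint (`AB`), or the heavy-atom centroid (`AVG`) —
and embedded in a sphere centred on its geometric centre *o*. The spherical
radius *R* is the distance of the outermost residue from *o*.

Inter-residue geometry is encoded in **(dis)similarity tensors**: an *n×n*
matrix of pairwise coefficients *z<sub>ij</sub>* (Euclidean, Manhattan,
Chebyshev, Minkowski, Canberra, Bray–Curtis, cosine or Tanimoto
dissimilarity) or an *n×n×n* array of triple coefficients *z<sub>ijl</sub>*
(triangle area, perimeter, bond angle, distance sum). The package's central
operation is **fuzzy spherical truncation** of these tensors:

    S(r) = r × F(W),        w_p = μ_A(d_p)

where *d<sub>p</sub>* is the distance of residue *p* to the centre,
*μ<sub>A</sub>* is one of 16 truncation functions defined on the interval
*A* = [*d*<sub>on</sub>, *d*<sub>off</sub>] = [*R·r*<sub>on</sub>,
*R·r*<sub>off</sub>], and *F* fuses the memberships of the 2 or 3 residues
in each tensor entry (arithmetic mean by default). The 13 fuzzy membership
functions (S-, Z-, PI-shaped, triangular, trapezoidal, two sigmoids, three
Gaussians, three generalized Bells) and 3 molecular-dynamics smoothing
functions (two shiftings, one switching) differ in whether they emphasize
residues near the centre, in the middle shell, or at the surface.

Truncated tensors then pass through the fixed pipeline — lag filters
(sequence-separation window `LGP`, Å-distance window `LGL`), residue-group
restriction (e.g. the beta-sheet-favouring `FBS` set), `NS`/`SS`/`MP`
normalization, Hadamard power *k* — and are split per residue. Bilinear /
trilinear forms weighted by amino-acid property scales (electronic charge
`ECI`, molecular volume `GVO`, Hopp–Woods `HWH`, Kyte–Doolittle `KDH`),

    L_aa = Σ_ij Z_aa[i,j]·x_i·y_j     (or Σ_ijl Z_aa[i,j,l]·x_i·y_j·p_l),

give a vector of Local Amino acid Invariants, which aggregation operators
(sum, means, norms, moments, quantiles) collapse into global descriptors.
Every descriptor carries a deterministic, parseable name, e.g.
`CA_N1_Q_EUCLIDEAN_SS-2_LGST(Z)[0.2-1]_ECI`.

Exploratory tooling mirrors the screening workflow: residue distance-bin
distributions over the spherical radius, descriptive statistics and Ward
clustering of the 16 truncation functions, Shannon-entropy variability
ranking, and varimax-rotated PCA loadings with a 0.7 strong-loading rule.

## Worked example

The classic worked fragment (first five residues of PDB entry 5WRX, Cβ
representation) has *R* = 4.056 Å; its innermost residue TRP5 sits at
*d* = 2.83 Å. On the full interval [0, *R*]:

```r
library(ProtSphere)
we <- workedExample()
membership("S_SHAPED",  we$dTRP5, 0, we$radius)   # 0.8172678
membership("Z_SHAPED",  we$dTRP5, 0, we$radius)   # 0.1827322
membership("PI_SHAPED", we$dTRP5, 0, we$radius)   # 0.7844477
```

The S-shaped function (surface-biased) keeps most of TRP5's interactions;
its Z-shaped complement (centre-biased) suppresses them; the PI-shaped
function rewards the middle shell. The outermost residue (VAL1, d = 4.06)
gets 1 / 0 / 0 respectively.

A full descriptor computation on a synthetic peptide:

```r
pep <- makeSyntheticPeptide(n = 8, placement = "uniform-ball", seed = 1)
sphericalFrame(pep)
#> SphericalFrame: center (0.000, 0.000, -0.000), R = 9.812 A, 8 residues

spec <- descriptorSpec("CA", "Q", "EUCLIDEAN", "SS", k = 2,
                       truncation = truncationSpec("Z_SHAPED", 0.2, 1),
                       properties = "ECI", aggregations = c("N1", "Q1"))
tf <- tempfile(fileext = ".pdb"); writePeptidePDB(pep, tf)
descriptorValues(computeDescriptors(list(pep1 = tf), spec))
#>      CA_N1_Q_EUCLIDEAN_SS-2_LGST(Z)[0.2-1]_ECI
#> pep1                                 0.7571125
#>      CA_Q1_Q_EUCLIDEAN_SS-2_LGST(Z)[0.2-1]_ECI
#> pep1                                 0.1235832
```

The two columns are the sum (`N1`) and quadratic mean (`Q1`) of the
per-residue bilinear forms of the Z-truncated, row-stochastic, squared
Euclidean distance matrix weighted by the electronic charge index. Rigid
motions of the input leave every column unchanged; a `NONE` truncation
reproduces the untruncated pipeline bit-exactly.

A thin command-line front end lives in `inst/scripts/protsphere-cli.R`
(subcommands `compute`, `name`, `validate-config`, `bins`,
`membership-stats`, `cluster-functions`, `entropy`, `pca`).

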