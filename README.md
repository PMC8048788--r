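# clamshell

Rigid-body domain motion analysis for two-lobe ("clam-shell") protein
structures.

Many enzymes gate access to a buried active site by swinging one
subdomain away from the other about a narrow hinge. The catalytic
domains of angiotensin-1-converting enzyme (ACE) and its homologue ACE2
are the motivating case: each is an α-helical ellipsoid of two
subdomains whose opening creates a deep groove to the active-site zinc.
`clamshell` is for structural biologists who have two or more
conformations of such a protein (PDB or mmCIF) and want to quantify the
motion between them: which regions move and by how much, where the
hinges are, what rotation carries one subdomain onto the other, and how
the interface contacts change.

## What it computes

Given a mobile and a reference conformation and a subdomain partition,
`domain_motion()`:

1. builds the residue correspondence over Cα atoms observed in both
   structures (author-number matching, or BLOSUM62 global alignment for
   homologues);
2. superposes the mobile chain on the reference's **anchor subdomain**
   (subdomain 2) by unweighted least squares (Kabsch: for paired,
   centred coordinate sets *P*, *Q* with covariance *H* = *PᵀQ* = *USVᵀ*,
   the optimal proper rotation is *R* = *V* diag(1, 1, det(*VUᵀ*)) *Uᵀ*),
   and also reports the global all-Cα fit RMSD;
3. profiles per-residue Cα displacement after the anchored fit and
   summarises each named mobile region (max, argmax, mean);
4. detects hinges as low-displacement runs flanked by high-displacement
   regions;
5. fits the residual rigid transform of subdomain 1 and decomposes it
   into a **screw axis** (Chasles): rotation angle θ from the trace of
   *R*, axis direction from the invariant eigenvector, axial
   translation, and a point on the axis — the opening angle and pivot
   line, ranked against the annotated hinges;
6. measures the displacement of tracked hetero atoms (e.g. the
   active-site Zn²⁺) under the anchored transform.

Separate detectors fingerprint interfaces: polar contacts (N/O/S pairs
≤ 3.4 Å), hydrophobic carbon contacts (apolar C pairs ≤ 3.9 Å), metal
coordination (≤ 2.8 Å) and water-mediated bridges (BFS through up to 3
ordered waters). `pairwise_rmsd_matrix()` builds the usual
open/closed comparison table across conformer sets.

The built-in `nace_scheme()` carries the ACE N-domain partition
(subdomain 1: residues 11–97, 272–417, 507–566; subdomain 2: 98–271,
418–506, 567–601; the lid 14–100, four mobile regions and eight hinge
annotations h0–h7, in author numbering).

A synthetic generator (`generate_clamshell()`) builds closed/open pairs
of idealised two-lobe Cα models with a known opening angle, axis, noise
level and interface metal, so the whole pipeline is testable with
analytic ground truth and no downloads.

## Worked example

```r
library(clamshell)

pair <- generate_clamshell(clamshell_spec(theta = 25, noise_sigma = 0.2, seed = 3))
fit  <- domain_motion(pair$open, pair$closed, pair$scheme)
fit
```

```
domain_motion: clamshell_open (mobile) vs clamshell_closed (reference), scheme 'clamshell'
  164 corresponded C-alpha pairs
  anchored fit (subdomain 2): RMSD 0.464 A (80 CA); global over all pairs: 21.579 A
  global least-squares fit: RMSD 8.381 A (164 CA)
  opening: 24.96 deg about axis [0.010, -0.002, 1.000], axial shift 0.01 A
  hetero displacement: ZN 1.75 A
```

Reading this: the anchor subdomain superposes to 0.464 Å (pure
coordinate noise, σ = 0.2 Å per model), while the same transform leaves
a 21.6 Å RMSD over all residues — the signature of a rigid-body
subdomain motion, not uniform distortion. The residual subdomain-1 fit
recovers the simulated 25° opening as 24.96° about an axis within 0.6°
of the true one, and the interface zinc moves 1.75 Å (analytic value
2·r·sin(θ/2) = 1.73 Å at r = 4 Å). The hinge detector calls residues
81–85, overlapping the true hinge loop 81–84:

```r
fit$hinges
#>   start_resno end_resno n mean_displacement flank_max    score
#> 1          81        85 5         0.4851548  4.203186 8.663596
```

`summary(fit)` adds the region table and the hinge-to-axis distances;
`plot(fit)` draws the displacement profile with regions shaded and
hinge calls marked; `coef(fit)` returns the screw parameters;
`residuals(fit)` the per-residue displacements.

For deposited structures the same analysis runs off files:

```r
open_n  <- read_structure(fetch_structure("6ZPQ"))   # open ACE N-domain
closed_n <- read_structure(fetch_structure("6F9V"))  # closed, inhibitor-bound
fit <- domain_motion(open_n, closed_n, nace_scheme())
```

(`fetch_structure()` downloads and caches from the RCSB; nothing in the
package or tests requires network access.)

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/clamshell.R simulate --theta 25 --sigma 0.2 --seed 3 --outdir sim
Rscript inst/cli/clamshell.R compare --mobile sim/open.pdb --reference sim/closed.pdb \
        --scheme sim/scheme.json --outdir out
Rscript inst/cli/clamshell.R matrix --inputs a.pdb,b.pdb,c.pdb --outdir out
Rscript inst/cli/clamshell.R contacts --input complex.pdb --peptide B --receptor A --outdir out
```

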