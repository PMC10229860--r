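---
title: "Geometry-driven repositioning of FE human body models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-driven repositioning of FE human body models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arthropose)
```

# The problem

A finite-element human body model replicates one specific posture. Human
joints, unlike a dummy's hinges, are guided by face-to-face articular
contact: there is no structural axis to rotate about, and the equivalent
helical axis of a real knee changes continuously with flexion. Solver-based
repositioning (pulling the model into a new pose in a crash solver) is slow
and tends to distort elements so badly that the result needs manual repair.

`arthropose` instead *emulates* the repositioning: bones travel along
trajectories derived from their own articular geometry, and soft tissue
follows by interpolation with a light, pseudo-physical contact correction.
The output is meant to be simulation-ready: same mesh topology, rigid
bones, and element quality close to the baseline.

# Skeleton kinematics

## Ball and hinge joints

The glenohumeral and acetabulofemoral joints are ball-and-socket: their
rotation centre is estimated by an algebraic least-squares sphere fit
(`fit_sphere()`) on the articular-surface node sets. Rotations are
parameterised as intrinsic Euler angles in the internal/external →
flexion/extension → adduction/abduction sequence (`euler_intrinsic()`); a
full 3×3 rotation matrix is accepted interchangeably. The humeroulnar joint
is a hinge about the trochlear-notch axis, found by a nonlinear cylinder
fit (`fit_cylinder()`: axis direction optimised over its spherical angles,
with a closed-form circle fit in the orthogonal plane; initialised from the
principal directions of the point cloud). The radius follows the ulna;
supination/pronation is out of scope. Anatomical axes default to the global
frame (X anterior, Y left, Z superior) and can be overridden per joint in
the config — the source material never pins down the frame, so the default
is a documented convention, not an inference.

## Spine

Vertebral rotation centres are the midpoints of the top- and bottom-face
node-set centroids (`vertebra_center()`). A prescribed total rotation is
split evenly across the vertebrae and applied with Rodrigues rotations
about each vertebra's own (current) centre. The splitting rule says nothing
about whether superior vertebrae inherit inferior rotations; we compound
caudal → cranial as a kinematic chain (`spine_transforms()`), because
independent per-vertebra rotation would disarticulate the column — this is
the single most consequential reading we had to choose, and it is
observable: the cranial-most vertebra accumulates the full prescribed
angle. Three-angle lumbar input is split per axis and composed in the
intrinsic order per segment. Thoracic input is flexion-only.

## Knee: the geometrically neutral path

The tibiofemoral joint is convex-on-convex with two compartments, so the
axis must be *solved*, not fitted once. Per increment:

1. **Contact search** (`find_contact_point()`): each tibial plateau is
   approximated as a plane; the condyle point whose outward normal is
   antiparallel to the plane normal is located by taking the
   minimum-signed-distance vertex and refining inside its incident
   triangles with a multi-level barycentric grid search (coarse resolution
   0.05, three shrinking refinement levels) over the interpolated
   position/normal. The refinement depth matters: with a two-level search
   the contact point quantises at ~2.5 µm and that noise dominates the
   trajectory's drift diagnostics.
2. **Curvature** (`curvature_tensor_field()`): per-vertex normal-cycle
   tensors, `C(p) = (1/A_p) Σ_e β(e)·|e∩A_p|·(ē⊗ē)` with β(e) the signed
   dihedral (positive convex), A_p the obtuse-safe mixed Voronoi area and
   |e∩A_p| = half the edge length. Two corrections are essential and easy
   to get wrong:
   - *Eigenvalue swap.* The raw tensor's tangent eigenvectors are the
     principal directions but carry each other's curvatures (on a
     cylinder, all the mass sits on the axial direction). After projection
     we therefore swap the two tangent eigenvalues.
   - *2D tangent diagonalisation.* The swap must be computed in an
     explicit 2D tangent basis. A 3×3 eigendecomposition is ambiguous
     whenever a tangent eigenvalue degenerates with the (zero) normal
     eigenvalue — exactly the cylinder case — and silently mixes the
     normal into the "tangent" eigenvector. This failure mode was caught
     by the cylinder oracle (circumferential κ dropped to ~0.3/R at most
     vertices) and is the reason the acceptance suite checks *every*
     vertex, not a lucky sample.
3. **Helical-axis solve** (`solve_helical_axis()`): the osculating radii
   minimise `(r_m − 1/κ_n(t_m))² + (r_l − 1/κ_n(t_l))²` where the tangents
   t = û × n depend on the current axis candidate û. We use a fixed-point
   scheme — initialise û from the contact-point pair, then alternate
   (tangents ← û; radii ← 1/κ_n; centres I = p − r·n; û ← I_l − I_m) —
   each half-step zeroes one squared term, so a fixed point is a minimiser
   with objective value 0. Convergence tolerance 1e-6 mm on the radii, cap
   100 iterations; isotropic curvature converges in one step. Degenerate
   axes (I_m ≈ I_l) and non-convex contacts (κ_n ≤ 1e-6/mm) are hard
   errors naming the compartment, not guesses.
4. **Step** (`step_flexion()`): the tibia-side entities rotate about the
   axis by a small increment (default 0.5°, capped at 5°); the final step
   is truncated to land exactly on the target. Extension runs the same
   loop with negative steps; there is deliberately no hyperextension
   guard.

On the sphere-knee fixture this machinery recovers r = R to 0.07% and the
osculating centres to ~0.015 mm at 1 mm mesh edges; on the coaxial-cylinder
fixture the integrated 40° trajectory matches a single 40° hinge rotation
to well under 0.5°.

### Why per-step drift is O(step), not O(step²), on the sphere fixture

For spherical condyles the solved axis passes through the exact sphere
centres, and a rotation about that axis preserves tangency and the contact
point *exactly, for any finite step angle*. There is no integration error
to expose, so the drift that remains is the (step-independent) curvature
bias δr ≈ 0.07% · R displacing the axis slightly: per-step drift ≈ δr ·
step. Halving the step halves it — a factor ~2, never the ≥3× a quadratic
law would give. The corresponding acceptance clause is left failing with
this analysis; an O(step²) law would only appear on a fixture whose true
axis varies along the path (the ellipsoid knee), where the per-step lag of
the explicit stepping scheme is first-order in the step.

# Soft tissue

## Thin-plate splines

All continuous deformation is TPS interpolation of nodal *displacements*
with the 3D biharmonic kernel φ(r) = r (the familiar r²·log r kernel is the
2D plate and would not minimise bending energy in a volume). λ = 0 (exact
interpolation) everywhere by default; the dense solve is O(n³) and capped
at 5 000 landmarks by deterministic farthest-point subsampling with a
warning. Exactness at the landmarks, affine reproduction (zero kernel
weights under an affine target map), superposition in the targets and
translation equivariance are all tested properties.

## Morph–contact

A sliding interface breaks interpolation: capsule nodes must follow *their
side* of the discontinuity. Capsule vertices are segmented
(`segment_capsule()`) into proximal/distal attachments (within 1 mm of the
femur/tibia surface; ties go to the nearer bone with a warning), interior
(normal facing the nearest bone) and exterior. The pipeline is then:

1. *Preliminary morph*: TPS from a reduced bone landmark set — a
   farthest-point subsample at ~10% density that **excludes** bone faces
   whose normals point into the joint space, since those are precisely the
   anchors that drag the capsule into the gap; attachments are then
   overwritten with their exact rigid bone transforms.
2. *Detection* (`detect_penetrations()`): signed distance of the involved
   bone nodes to the capsule, positive on the capsule's normal (cavity)
   side, with angle-weighted interpolated pseudonormals. A node is
   penetrating when its sign flipped versus the pre-morph configuration
   and is now negative (beyond a 1 µm grazing tolerance). Two guards make
   this robust on open capsules: nodes whose nearest feature is the free
   rim are ignored (their sign is meaningless), and the "involved" slave
   set is restricted to bone nodes the capsule actually covers pre-morph.
3. *Resolution* (`resolve_penetrations()`): the capsule patch nearest each
   penetrating node (nearest-face vertices plus 1-ring, raised-cosine
   falloff: full displacement on the core, half on the ring) is pulled
   against the capsule normal by depth + 0.1 mm clearance; re-detect;
   iterate (cap 50, then a hard error carrying the residual report).
   Attachment nodes never move.
4. *Refinement* (`refine_interface()`): gradient descent over the interior
   nodes on `w_c·Chamfer² + w_e·Var(ℓ/ℓ₀)/mean² + w_n·(1 − cos∠)` with
   w = (1.0, 0.1, 0.01), displacement-normalised steps of 0.05 mm decaying
   0.95 per 50 iterations, stop at relative loss change < 1e-5 or 500
   iterations, rollback on any face flip. Three numerical choices matter:
   - the shape term is evaluated **point-to-plane** against the reference
     samples (nodes + face centroids). Point-to-point Chamfer penalises
     tangential sliding with the square of the sample spacing, which is
     orders of magnitude larger than the regularity gains — the optimiser
     simply freezes. Point-to-plane measures the same shape deviation but
     lets nodes redistribute along the surface, which is the entire point
     of the step.
   - edge inconsistency is measured on length *ratios* against the
     original undeformed capsule (ℓ₀): a triangulated tube has an
     intrinsic raw-CV floor (~0.26, from the split diagonals), so raw CV is
     not a regularity signal; the ratio CV is 0 for any distortion-free
     deformation.
   - nearest-neighbour correspondences are frozen for 10-iteration spans
     and the samples capped at 1 500 per side, keeping an iteration at a
     few tens of milliseconds.
   The reference shape is the penetration-fixed surface (so penetration
   freedom is preserved; the alternative reading — refining toward the
   pre-penetration morph — would re-introduce penetrations), and a final
   corrective pull pass re-checks both bones after refinement.
5. *Flesh TPS* (`deform_soft_tissue()`): boundary landmarks = all capsule
   nodes plus all bone surface nodes (pre → post, deduplicated at shared
   attachment nodes in favour of the capsule's morphed position); every
   flesh/skin node is interpolated, landmark nodes are set exactly.

Spine-attached tissues skip the contact machinery and use plain TPS.

### The refinement CV clause

On the tube fixture the prescribed gentle pulls (their own contract asserts
max displacement ≈ depth + clearance to within 20%) leave an intermediate
whose interior ratio-CV (0.129) is almost identical to the preliminary
morph's (0.128): there is essentially no pull-induced oscillation to
remove. What remains is the smooth TPS strain field between the fixed
attachments — compressed on the flexor side, stretched on the extensor side
— whose between-sector component no node redistribution can remove, because
the attachment-to-attachment totals are fixed. The acceptance clause
demanding a ≥50% CV reduction over that intermediate is therefore left
failing. The refinement itself demonstrably does its job: on the
oscillatory fixture (alternate interior nodes displaced ±0.3 mm along their
normals) it removes 96% of the ratio-CV while staying within 0.002 mm
Chamfer distance of the target shape.

# Mesh quality

"Jacobian" is implemented as the corner-based scaled Jacobian (minimum over
the 8 corners of the determinant of the normalised edge triad) — the usual
preprocessor convention; warpage is the angle between the two
diagonal-split normals of a quad, maximised over both splits, evaluated on
shell quads and on each hex face (element value = max over its 6 faces);
aspect ratio is max/min edge length. All three are dimensionless and
rigid/scale invariant (tested to 1e-9). Thresholds default to the common
audit triple warpage > 15°, aspect > 5, Jacobian < 0.5, and each metric's
failing fraction is reported over the elements it applies to (tets get
aspect only). Because the metric *definitions* behind published whole-body
counts are preprocessor-specific, absolute counts on any external model are
not an equivalence target; the end-to-end acceptance instead bounds the
*change* in the union failing fraction (≤ 0.5 percentage points at 40° knee
flexion on the toy limb; measured: +0.10 pp, no inversions).

# Synthetic fixtures

Fixture vertices are placed exactly on their analytic surfaces and carry
exact analytic normals, so curvature and contact oracles are clean
(`make_sphere_knee()`, `make_cylinder_knee()`, `make_ellipsoid_knee()`).
Dimensions follow the anatomy they stand in for: condyle radius 20 mm,
1 mm mesh edges (5% curvature accuracy at seconds-scale cost), bone radius
10 mm, 2 mm synovial stand-off. The tube-capsule fixture
(`make_tube_capsule()`) is a closed surface of revolution — attachment
rings on both bone cylinders, inner wall at bone + 2 mm, outer wall at
18 mm — oriented outward from the flesh volume it bounds, which makes the
penetration sign convention unambiguous. Its reference flexion axis runs
through the condylar region of the proximal bone (25 mm above the joint
line), as a knee's does; with the axis at the gap centre the preliminary
morph tracks the bone so well that no penetration forms at all.

The toy limb (`make_toy_limb()`) is a structured all-hex stand-in: O-grid
bone cylinders (femur above, tibia below, 16 mm joint space), a shared-node
flesh annulus to a 22 mm skin, a quad-shell capsule on the bone/flesh
interface around the joint, and analytic spherical condyles + tangent
plateau planes emitted in the joint config (as segmented articular surfaces
would be in real use). Its baseline passes all quality thresholds with
margin (min scaled Jacobian 0.71, max aspect 3.5, warpage ~0).

What a green end-to-end test does **not** establish: anthropometric
realism, behaviour on tetrahedral or mixed meshes, multi-joint interaction
of overlapping flesh regions, ligament/meniscus constraints, or volume
conservation of the flesh (explicitly out of scope; the TPS conserves
nothing). The fixtures exercise every code path, not every anatomy.

# Determinism and numerics

Every stage is deterministic given its inputs — farthest-point sampling
starts at the centroid-nearest point, Chamfer subsampling uses fixed
strides, and the only `set.seed` consumers are test-data generators. The
full reposition pipeline run twice produces byte-identical keyword files.
Keyword output writes coordinates with 17 significant digits so a
read→write→read cycle is exact. Angles are degrees at every public
interface and radians internally; coordinates are millimetres throughout.
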