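# pholiage

Whole-crown light capture and net photosynthesis of an individual tree
standing in — and liberated from — surrounding vegetation.

## What it is for

On degraded tropical land, young trees are often overgrown by grasses,
shrubs and lianas. *Liberation* — clearing the vegetation in a radius
around a target tree — is a standard restoration measure, but its effect
depends on the tree's stature, crown architecture and leaf physiology
and on the height and density of the vegetation. `pholiage` is a 3D
canopy model for exactly that configuration: one tree with an
ellipsoidal crown inside a homogeneous vegetation layer, with an
optional cylindrical gap of chosen radius cleared around the stem. It is
aimed at plant ecophysiologists and restoration ecologists who want to
compare species' responses to liberation, or to size gaps, before (or
instead of) cutting.

## The model in brief

Diffuse light from a discretized overcast sky (sectors *s* with beam
irradiance *B*<sub>s</sub>, normalized so horizontal irradiance above
the canopy is *I*<sub>o</sub>) is traced to points *p* inside the crown.
A beam at elevation β is attenuated through vegetation and crown by
Beer–Lambert extinction,

&nbsp;&nbsp;*T* = exp[ −*G*<sub>v</sub>(β)·lad<sub>v</sub>·*s*<sub>v</sub> −
*G*<sub>t</sub>(β)·lad<sub>t</sub>·*s*<sub>t</sub> ],

with exact ray–slab / ray–cylinder / ray–ellipsoid path lengths
*s*<sub>v</sub>, *s*<sub>t</sub> and leaf-angle projection functions
*G*(β). Absorbed flux per unit leaf area is
φ<sub>p</sub> = Σ<sub>s</sub> *B*<sub>s</sub>·*G*<sub>t</sub>(β<sub>s</sub>)·*T*<sub>s</sub>.
Leaf nitrogen follows the light gradient,
*N* = *N*<sub>o</sub>·(*I*/*I*<sub>o</sub>)<sup>0.4</sup>;
photosynthetic capacity is *P*<sub>max</sub> = *a*·*N*; the leaf light
response is a non-rectangular hyperbola with curvature θ (default 0.7),
apparent quantum yield φ<sub>q</sub> and dark respiration *R*<sub>d</sub>.
Integrating per-area rates over the crown volume and scaling by leaf
area gives whole-crown light capture Φ and net photosynthesis *P*
(μmol s⁻¹) and their per-leaf-area efficiencies Φ<sub>area</sub>,
*P*<sub>area</sub> (μmol m⁻² s⁻¹).

Parameter tables for three South-East Asian pioneer species (*Mallotus
microcarpus*, *Mallotus paniculatus*, *Macaranga denticulata*) and three
successional vegetation stands are packaged, together with a seeded
synthetic-scene generator and a YAML/JSON configuration interface. See
the methods vignette (`vignettes/pholiage-methods.Rmd`) for assumptions,
numerical choices and known limitations.

## Worked example

Liberate the mean *Macaranga denticulata* tree in the 1.5-year-old stand
(vegetation 1.40 m tall, LAI 3.73) with the field-trial gap radius of
0.5 m, under a uniform overcast sky of 1000 μmol m⁻² s⁻¹:

```r
library(pholiage)

sp    <- species_setup()[["Macaranga denticulata"]]
stand <- stand_setup("III")
lib   <- simulate_liberation(sp$tree, sp$physiology, stand, r_gap = 0.5)
lib$control
#> Crown result (leaf area 0.11 m^2):
#>   light capture  Phi = 23.16 umol s^-1   Phi_area = 210.6 umol m^-2 s^-1
#>   photosynthesis P   = 0.5139 umol s^-1   P_area   = 4.672 umol m^-2 s^-1
lib$liberated
#> Crown result (leaf area 0.11 m^2):
#>   light capture  Phi = 43.62 umol s^-1   Phi_area = 396.5 umol m^-2 s^-1
#>   photosynthesis P   = 0.7975 umol s^-1   P_area   = 7.25 umol m^-2 s^-1
```

Clearing a 0.5 m radius nearly doubles the light absorbed per unit leaf
area (211 → 397 μmol m⁻² s⁻¹) and raises net photosynthesis per leaf
area from 4.7 to 7.3 μmol CO₂ m⁻² s⁻¹ — the crown sits 0.3 m below the
vegetation top, so most of the gain comes from oblique light that the
intact canopy intercepts. The gap-radius response and its saturation:

```r
gap_radius_sweep(sp$tree, sp$physiology, stand,
                 radii = c(0, 0.25, 0.5, 1, 2.5))
#>  gap_radius   Phi    P Phi_area P_area Phi_pct  P_pct
#>        0.00 23.16 0.51   210.58   4.67   33.81  48.63
#>        0.25 32.43 0.65   294.86   5.92   47.34  61.61
#>        0.50 43.62 0.80   396.52   7.25   63.66  75.47
#>        1.00 55.95 0.94   508.67   8.51   81.67  88.54
#>        2.50 68.51 1.06   622.86   9.61  100.00 100.00
```

`Phi_pct`/`P_pct` express each radius as a percentage of the 2.5 m
value: most of the benefit is realized by ~1 m, but under a homogeneous
vegetation slab the last fraction — low-elevation sky light — recovers
slowly with radius (see the vignette for why this makes the model's
radius requirements conservative).

The same runs are available from a shell via the thin wrapper
`inst/cli/pholiage.R`:

```sh
Rscript inst/cli/pholiage.R gap-sweep \
  --config inst/extdata/example_config.yaml --out results/
```

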