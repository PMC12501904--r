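# Observer table provenance

`observer_tables_5nm.csv` tabulates the spectral weighting functions of
the circadian phototransduction model on 380-780 nm at 5 nm.  The file
is generated by `cswear::write_observer_tables()` from the analytic
definitions in `R/observers.R` and verified at load time against the
md5 checksum in `observer_tables_manifest.txt`.

Columns and sources:

| column | function | construction |
|---|---|---|
| `xbar`, `ybar`, `zbar` | CIE 1931 2-degree color-matching functions | multi-Gaussian analytic fits (Wyman, Sloan & Shirley, JCGT 2013) |
| `v` | photopic luminous efficiency | `ybar` normalized to 1.0 at its 555 nm peak |
| `vprime` | scotopic luminous efficiency | Govardovskii et al. (2000) A1 pigment nomogram, lambda_max 500 nm, filtered by the synthetic lens transmittance, peak-normalized |
| `mc` | melanopsin sensitivity corrected for crystalline-lens transmittance | A1 nomogram, lambda_max 480 nm, times lens transmittance, peak-normalized |
| `scone` | S-cone fundamental | A1 nomogram, lambda_max 440 nm, times lens and macular transmittance, peak-normalized |
| `mp` | macular pigment transmittance | SYNTHETIC: 10^(-0.35 * Gaussian(460 nm, sigma 26 nm)) |

Lens transmittance (used inside `vprime`, `mc`, `scone`) is SYNTHETIC:
optical density `0.60 * exp(-(lambda - 400)/49)`, a smooth monotone
stand-in matching the qualitative shape of published lens density
curves.

These tables are documented stand-ins for the laboratory tabulations
the model was originally published with (which are not redistributed
here).  Band positions, normalizations and all structural invariants
(V peaks at 555 nm = 1; V' peaks near 507 nm = 1; mp strictly
positive) are enforced by `validate_observer_tables()` and by the test
suite; absolute circadian-light values computed with them will differ
from implementations using the original tabulations.
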