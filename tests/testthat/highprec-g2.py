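"""50-digit re-evaluation of the semi-infinite correlation-diffusion g2.

Reads a JSON list of parameter sets on stdin, each with mu_a, mu_s, rho,
wavelength_cm, n_medium, reff, alpha_db, beta and a taus list; derives the
model constants independently and prints the g2 values per set as JSON.
"""
import sys
import json
from mpmath import mp, mpf, sqrt, exp, pi

mp.dps = 50

out = []
for c in json.load(sys.stdin):
    mu_a = mpf(repr(c["mu_a"]))
    mu_s = mpf(repr(c["mu_s"]))
    rho = mpf(repr(c["rho"]))
    lam = mpf(repr(c["wavelength_cm"]))
    n = mpf(repr(c["n_medium"]))
    reff = mpf(repr(c["reff"]))
    a = mpf(repr(c["alpha_db"]))
    b = mpf(repr(c["beta"]))

    A = 3 * mu_s * mu_a
    k0 = 2 * pi * n / lam
    B = 6 * mu_s ** 2 * k0 ** 2
    z0 = 1 / mu_s
    r1 = sqrt(z0 ** 2 + rho ** 2)
    zb = (2 / (3 * mu_s)) * (1 + reff) / (1 - reff)
    rb = sqrt((2 * zb + z0) ** 2 + rho ** 2)
    H = exp(-r1 * sqrt(A)) / r1 - exp(-rb * sqrt(A)) / rb

    vals = []
    for tau in c["taus"]:
        K = sqrt(A + B * a * mpf(repr(tau)))
        g1 = (exp(-r1 * K) / r1 - exp(-rb * K) / rb) / H
        vals.append(float(1 + b * g1 * g1))
    out.append(vals)

json.dump(out, sys.stdout)
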