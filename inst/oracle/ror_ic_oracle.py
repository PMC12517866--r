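#!/usr/bin/env python
"""High-precision oracle for the 2x2 disproportionality formulas.

Reads a CSV of integer counts a,b,c,d (with header) and writes a CSV of
ror, ci_low, ci_high, ic computed with 50-significant-digit arithmetic:

    ROR   = a*d / (b*c)
    95%CI = exp(ln(ROR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))
    IC    = log2(a * n / ((a + b) * (a + c))),  n = a + b + c + d

Usage: python ror_ic_oracle.py tables.csv out.csv
"""
import csv
import sys

import sympy as sp


def main(inp, outp):
    rows = []
    with open(inp, newline="") as fh:
        for rec in csv.DictReader(fh):
            a, b, c, d = (sp.Integer(int(rec[k])) for k in "abcd")
            n = a + b + c + d
            ror = sp.Rational(a * d, b * c)
            half = sp.Rational(196, 100) * sp.sqrt(
                sp.Rational(1, a) + sp.Rational(1, b)
                + sp.Rational(1, c) + sp.Rational(1, d))
            lo = sp.exp(sp.log(ror) - half)
            hi = sp.exp(sp.log(ror) + half)
            ic = sp.log(sp.Rational(a * n, (a + b) * (a + c)), 2)
            rows.append([sp.N(v, 50) for v in (ror, lo, hi, ic)])
    with open(outp, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["ror", "ci_low", "ci_high", "ic"])
        for r in rows:
            w.writerow([format(float(v), ".17g") for v in r])


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
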