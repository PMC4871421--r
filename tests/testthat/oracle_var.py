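"""Reference VAR/ADF computations via statsmodels, used as an independent
oracle by the R test suite.

Reads a job spec JSON: {"tasks": [{"id":..., "kind": "var"|"adf",
 "csv": path, "k": order, "H": horizon} ...]}, writes one JSON with, per id:
for "var": intercept, coefficient matrices, sigma_u, irf, orth irf, fevd;
for "adf": tau statistic, used lags, MacKinnon p-value.
"""
import json
import sys

import numpy as np
import pandas as pd
from statsmodels.tsa.api import VAR
from statsmodels.tsa.stattools import adfuller


def run_var(task):
    y = pd.read_csv(task["csv"]).values
    k = int(task["k"])
    horizon = int(task.get("H", 10))
    res = VAR(y).fit(k, trend="c")
    irf = res.irf(horizon)
    fevd = res.fevd(horizon)
    return {
        "intercept": res.intercept.tolist(),
        "coefs": res.coefs.tolist(),
        "sigma_u": np.asarray(res.sigma_u).tolist(),
        "irf": irf.irfs.tolist(),
        "orth_irf": irf.orth_irfs.tolist(),
        "fevd": fevd.decomp.tolist(),
    }


def run_adf(task):
    x = pd.read_csv(task["csv"]).values[:, 0]
    regression = {"constant": "c", "trend": "ct"}[task.get("variant", "constant")]
    maxlag = task.get("max_lags")
    stat, pval, usedlag, nobs, _, _ = adfuller(
        x, maxlag=None if maxlag is None else int(maxlag),
        regression=regression, autolag="AIC")
    return {"tau": stat, "lags": int(usedlag), "p_value": pval}


def main(spec_path, out_path):
    with open(spec_path) as fh:
        spec = json.load(fh)
    out = {}
    for task in spec["tasks"]:
        out[task["id"]] = run_var(task) if task["kind"] == "var" else run_adf(task)
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
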