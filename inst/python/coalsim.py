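"""Coalescent simulation backend.

Invoked as a subprocess:  python coalsim.py <config.json> <out.json>

Runs msprime coalescent-with-recombination simulations (optionally with
non-crossover gene conversion and/or Beta-coalescent multiple mergers),
overlays binary mutations, applies site ascertainment (biallelic,
polymorphic in a reference subsample), and extracts exact genealogical
ground truth: per-pair piecewise-constant TMRCA segments and the
span-weighted mean pairwise TMRCA matrix.

All coordinates emitted are raw tskit 0-based bp ("breaks") except site
positions, emitted 1-based ("positions"). All haplotype/pair indices are
0-based here; the R caller converts.
"""

import json
import sys

import numpy as np
import msprime
import tskit


def listify(x):
    """JSON length-1 arrays may arrive as bare scalars."""
    return x if isinstance(x, list) else [x]


def build_demography(spec):
    times = listify(spec["times"])
    sizes = listify(spec["sizes"])
    dem = msprime.Demography()
    dem.add_population(name="pop", initial_size=sizes[0])
    for t, s in zip(times[1:], sizes[1:]):
        dem.add_population_parameters_change(time=t, initial_size=s,
                                             population="pop")
    return dem


def build_rate_map(spec, length):
    if "map" in spec and spec["map"] is not None:
        m = spec["map"]
        return msprime.RateMap(position=listify(m["positions"]),
                               rate=listify(m["rates"]))
    return spec["rate"]


def pair_index(n):
    """Unordered pairs (i < j) in row-major order, matching R combn()."""
    return [(i, j) for i in range(n - 1) for j in range(i + 1, n)]


def tmrca_segments(ts, pairs):
    """Per-pair piecewise TMRCA along the genome, merged on equal values.

    Returns {pair: (breaks, tmrcas)} with breaks the left bp edge of each
    segment (first always 0.0).
    """
    pairs = [tuple(p) for p in pairs]
    out = {}
    for p in pairs:
        breaks, tmrcas = [], []
        cur = None
        for tree in ts.trees():
            if tree.num_roots != 1:
                raise RuntimeError(
                    "tree with multiple roots; cannot label TMRCA")
            t = tree.tmrca(p[0], p[1])
            if cur is None:
                breaks.append(0.0)
                tmrcas.append(t)
                cur = t
            elif t != cur:
                breaks.append(tree.interval.left)
                tmrcas.append(t)
                cur = t
        out[p] = (breaks, tmrcas)
    return out


def mean_tmrca_matrix(ts, n):
    idx = pair_index(n)
    div = ts.divergence([[i] for i in range(n)], indexes=idx, mode="branch",
                        span_normalise=True)
    return (np.asarray(div) / 2.0).tolist()


def run_sim(spec):
    seed = int(spec["seed"])
    n_hap = int(spec["n_haplotypes"])
    length = float(spec["length"])
    model = None
    if spec.get("beta_alpha") is not None:
        model = msprime.BetaCoalescent(alpha=float(spec["beta_alpha"]))
    kwargs = {}
    gc_rate = float(spec.get("gc_rate") or 0.0)
    if gc_rate > 0:
        kwargs["gene_conversion_rate"] = gc_rate
        kwargs["gene_conversion_tract_length"] = float(spec["gc_tract"])
    ts = msprime.sim_ancestry(
        samples=n_hap // 2,
        demography=build_demography(spec["demography"]),
        sequence_length=length,
        recombination_rate=build_rate_map(spec["recombination"], length),
        ploidy=2,
        model=model,
        random_seed=seed,
        **kwargs,
    )
    mu = float(spec["mutation_rate"])
    if mu > 0:
        ts = msprime.sim_mutations(
            ts, rate=mu, random_seed=seed,
            model=msprime.BinaryMutationModel(), discrete_genome=True)

    out = {"seed": seed, "n_haplotypes": n_hap, "length": length}

    # --- site ascertainment -------------------------------------------------
    G = ts.genotype_matrix()            # sites x haplotypes, 0/1 under binary model
    pos = ts.tables.sites.position
    nmut = np.bincount(ts.tables.mutations.site, minlength=ts.num_sites)
    dac = G.sum(axis=1)
    keep = (dac > 0) & (dac < n_hap)
    ref = spec.get("ref_subsample")
    if ref is not None and 2 * int(ref) < n_hap:
        rng = np.random.default_rng(seed + 10_000_019)
        inds = rng.choice(n_hap // 2, size=int(ref), replace=False)
        haps = np.sort(np.concatenate([2 * inds, 2 * inds + 1]))
        sub = G[:, haps].sum(axis=1)
        keep &= (sub > 0) & (sub < len(haps))
    keep_idx = np.flatnonzero(keep)
    G = G[keep_idx]
    if spec.get("want_panel", True):
        out["positions"] = (pos[keep_idx].astype(np.int64) + 1).tolist()
        out["haplotypes"] = ["".join(row) for row in
                             G.T.astype("U1")]
        out["n_mut"] = nmut[keep_idx].tolist()
        if spec.get("want_mut_times", False):
            mt = np.full(ts.num_sites, np.nan)
            for site in ts.sites():
                if len(site.mutations) == 1:
                    mt[site.id] = site.mutations[0].time
            out["mut_time"] = [None if np.isnan(x) else x
                               for x in mt[keep_idx]]
    if spec.get("want_divergence", False):
        out["mean_tmrca"] = mean_tmrca_matrix(ts, n_hap)
    pairs = spec.get("pairs", "none")
    if pairs == "all":
        pairs = pair_index(n_hap)
    elif isinstance(pairs, list):
        pairs = [listify(p) for p in pairs]
    if pairs != "none" and len(pairs) > 0:
        segs = tmrca_segments(ts, pairs)
        out["labels"] = [
            {"h1": p[0], "h2": p[1],
             "breaks": segs[p][0], "tmrcas": segs[p][1]}
            for p in (tuple(q) for q in pairs)
        ]
    if spec.get("save_trees"):
        ts.dump(spec["save_trees"])
    return out


def run_labels(job):
    ts = tskit.load(job["trees"])
    pairs = [tuple(listify(p)) for p in listify(job["pairs"])]
    segs = tmrca_segments(ts, pairs)
    return {"labels": [
        {"h1": p[0], "h2": p[1], "breaks": segs[p][0], "tmrcas": segs[p][1]}
        for p in pairs
    ]}


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    if cfg["mode"] == "simulate":
        res = {"sims": [run_sim(s) for s in cfg["sims"]]}
    elif cfg["mode"] == "labels":
        res = {"jobs": [run_labels(j) for j in cfg["jobs"]]}
    else:
        raise ValueError("unknown mode: %s" % cfg["mode"])
    with open(sys.argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
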