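"""Coalescent window simulator bridge.

Reads a JSON job file describing demographic models and replicate counts,
simulates with msprime, and writes a TSV of per-site derived-allele counts
(mode=counts) or per-chromosome haplotypes (mode=haplotypes).

Usage: python sim_windows.py <jobs.json>
"""
import json
import sys

import numpy as np
import pandas as pd
import msprime


def build_demography(m):
    dem = msprime.Demography()
    for name, pop in m["populations"].items():
        times = pop["times"]
        sizes = pop["sizes"]
        dem.add_population(name=name, initial_size=sizes[0])
        for t, s in zip(times[1:], sizes[1:]):
            dem.add_population_parameters_change(time=t, population=name, initial_size=s)
    for sp in m.get("splits") or []:
        dem.add_population_split(time=sp["time"], derived=sp["derived"], ancestral=sp["ancestral"])
    for p in m.get("pulses") or []:
        dem.add_mass_migration(time=p["time"], source=p["source"], dest=p["dest"], proportion=p["proportion"])
    for mig in m.get("migrations") or []:
        dem.set_migration_rate(source=mig["source"], dest=mig["dest"], rate=mig["rate"])
    dem.sort_events()
    return dem


def run_job(job, discrete, mode, out_rows):
    m = job["model"]
    dem = build_demography(m)
    pops = list(m["samples"].keys())
    sample_sets = [msprime.SampleSet(int(m["samples"][p]), population=p, ploidy=1) for p in pops]
    L = float(job["sequence_length"])
    reps = int(job["n_reps"])
    anc_seed = int(job["seed"])
    rng = np.random.RandomState(anc_seed)
    seeds = rng.randint(1, 2**31 - 1, size=(reps, 2))
    ts_iter = msprime.sim_ancestry(
        samples=sample_sets,
        demography=dem,
        sequence_length=L,
        recombination_rate=float(m["recombination_rate"]),
        discrete_genome=discrete,
        ploidy=2,
        num_replicates=reps,
        random_seed=anc_seed,
    )
    # offsets of each population's chromosomes in the genotype matrix
    sizes = [int(m["samples"][p]) for p in pops]
    offs = np.concatenate([[0], np.cumsum(sizes)])
    for rep, ts in enumerate(ts_iter):
        mts = msprime.sim_mutations(
            ts,
            rate=float(m["mutation_rate"]),
            model=msprime.BinaryMutationModel(),
            discrete_genome=discrete,
            random_seed=int(seeds[rep, 1]),
        )
        if mts.num_sites == 0:
            continue
        G = mts.genotype_matrix()  # sites x chromosomes, 0/1
        pos = mts.tables.sites.position
        seg = (G.sum(axis=1) > 0) & (G.sum(axis=1) < G.shape[1])
        if not seg.all():
            G = G[seg]
            pos = pos[seg]
        if G.shape[0] == 0:
            continue
        if mode == "counts":
            cols = {"job": job["id"], "rep": rep, "pos": pos}
            for i, p in enumerate(pops):
                cols["n_" + p] = G[:, offs[i]:offs[i + 1]].sum(axis=1)
            out_rows.append(pd.DataFrame(cols))
        else:
            gt = np.apply_along_axis(lambda r: "".join(map(str, r)), 1, G)
            out_rows.append(pd.DataFrame({"job": job["id"], "rep": rep, "pos": pos, "gt": gt}))


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    mode = cfg.get("mode", "counts")
    discrete = bool(cfg.get("discrete", False))
    out_rows = []
    for job in cfg["jobs"]:
        run_job(job, discrete, mode, out_rows)
    if out_rows:
        df = pd.concat(out_rows, ignore_index=True)
    else:
        cols = ["job", "rep", "pos"] + (["gt"] if mode == "haplotypes" else [])
        df = pd.DataFrame(columns=cols)
    df.to_csv(cfg["out"], sep="\t", index=False, float_format="%.6f")


if __name__ == "__main__":
    main()
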