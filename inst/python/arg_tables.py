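"""Bridge between msprime/tskit and the R package.

Exports tree-sequence tables as delimited text so that the R side never
parses the binary .trees format, and runs coalescent simulations with the
demographies used by the simulation harness.
"""

import argparse
import json
import os
import sys


def write_tables(ts, outdir):
    os.makedirs(outdir, exist_ok=True)
    with open(os.path.join(outdir, "meta.json"), "w") as f:
        json.dump(
            {
                "sequence_length": ts.sequence_length,
                "n_nodes": ts.num_nodes,
                "n_edges": ts.num_edges,
                "n_samples": ts.num_samples,
                "n_trees": ts.num_trees,
                "n_mutations": ts.num_mutations,
            },
            f,
        )
    with open(os.path.join(outdir, "nodes.tsv"), "w") as f:
        f.write("id\ttime\tis_sample\tindividual\n")
        for n in ts.nodes():
            f.write(
                f"{n.id}\t{n.time:.17g}\t{1 if n.is_sample() else 0}\t"
                f"{n.individual}\n"
            )
    with open(os.path.join(outdir, "edges.tsv"), "w") as f:
        f.write("left\tright\tparent\tchild\n")
        for e in ts.edges():
            f.write(f"{e.left:.17g}\t{e.right:.17g}\t{e.parent}\t{e.child}\n")
    if ts.num_mutations > 0:
        with open(os.path.join(outdir, "mutations.tsv"), "w") as f:
            f.write("position\tnode\n")
            for site in ts.sites():
                for mut in site.mutations:
                    f.write(f"{site.position:.17g}\t{mut.node}\n")


def cmd_dump(args):
    import tskit

    ts = tskit.load(args.trees)
    write_tables(ts, args.out)


def build_demography(args):
    import msprime

    if args.n_demes > 1:
        # linear stepping-stone of equal-size demes
        demography = msprime.Demography()
        for d in range(args.n_demes):
            demography.add_population(
                name=f"deme{d}", initial_size=args.ne / args.n_demes
            )
        for d in range(args.n_demes - 1):
            demography.set_migration_rate(
                f"deme{d}", f"deme{d + 1}", args.migration_rate
            )
            demography.set_migration_rate(
                f"deme{d + 1}", f"deme{d}", args.migration_rate
            )
        return demography
    demography = msprime.Demography()
    growth = args.growth_rate if args.demography == "decline" else 0.0
    demography.add_population(
        name="pop0", initial_size=args.ne, growth_rate=growth
    )
    return demography


def cmd_simulate(args):
    import msprime

    demography = build_demography(args)
    if args.n_demes > 1:
        per = args.n_diploids // args.n_demes
        extra = args.n_diploids - per * args.n_demes
        samples = {
            f"deme{d}": per + (1 if d < extra else 0)
            for d in range(args.n_demes)
        }
    else:
        samples = {"pop0": args.n_diploids}
    ts = msprime.sim_ancestry(
        samples=samples,
        demography=demography,
        sequence_length=args.sequence_length,
        recombination_rate=args.recombination_rate,
        random_seed=args.seed,
        ploidy=2,
    )
    if args.mutation_rate > 0:
        ts = msprime.sim_mutations(
            ts, rate=args.mutation_rate, random_seed=args.seed + 1,
            model=msprime.BinaryMutationModel(),
        )
    write_tables(ts, args.out)


def main(argv=None):
    p = argparse.ArgumentParser(description=__doc__)
    sub = p.add_subparsers(dest="command", required=True)

    d = sub.add_parser("dump", help="export a .trees file as TSV tables")
    d.add_argument("--trees", required=True)
    d.add_argument("--out", required=True)
    d.set_defaults(func=cmd_dump)

    s = sub.add_parser("simulate", help="coalescent simulation")
    s.add_argument("--n-diploids", type=int, required=True)
    s.add_argument("--sequence-length", type=float, default=1e6)
    s.add_argument("--recombination-rate", type=float, default=1e-8)
    s.add_argument(
        "--demography", choices=["decline", "constant"], default="decline"
    )
    s.add_argument("--ne", type=float, default=1e5)
    s.add_argument("--growth-rate", type=float, default=0.01)
    s.add_argument("--mutation-rate", type=float, default=0.0)
    s.add_argument("--n-demes", type=int, default=1)
    s.add_argument("--migration-rate", type=float, default=0.0)
    s.add_argument("--seed", type=int, default=1)
    s.add_argument("--out", required=True)
    s.set_defaults(func=cmd_simulate)

    args = p.parse_args(argv)
    args.func(args)


if __name__ == "__main__":
    sys.exit(main())
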