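# Significant SNP loci from a genome-wide donor-recipient mismatch association
# scan of corneal graft outcome in three semi-inbred pig lines (61 loci:
# 57 rejection-associated, 4 acceptance-associated).
# Coordinates: Sscrofa 10.2 assembly (Ensembl release 83).
# position_bp 0 = chromosomal position unknown; chromosome 0 = chromosome unknown.
# alt_chromosome: chromosome assignment under the earlier Sscrofa 9 assembly,
# recorded where it differs from the 10.2 assignment.
# position_alt_bp: second published position where two were given for one locus.
# model1 = directional (host-versus-graft) mismatch model; model2 = symmetric.
chromosome	position_bp	position_alt_bp	model1	model2	direction	alt_chromosome
1	132826911	0	0	1	rejection	NA
1	133258994	0	0	1	rejection	NA
1	133099036	0	0	1	rejection	NA
1	133084921	0	0	1	rejection	NA
1	133326538	0	0	1	rejection	NA
1	133472365	0	0	1	rejection	NA
1	134378501	0	0	1	rejection	NA
1	134796719	0	0	1	rejection	NA
1	135375075	0	0	1	rejection	NA
1	0	0	0	1	rejection	NA
1	0	0	0	1	rejection	NA
1	135569814	0	0	1	rejection	NA
1	135930910	136076989	0	1	rejection	NA
1	136240599	0	0	1	rejection	NA
1	136427159	0	0	1	rejection	NA
1	136639460	0	0	1	rejection	NA
1	136780600	0	0	1	rejection	NA
1	137134551	0	0	1	rejection	NA
1	137512402	0	0	1	rejection	NA
1	137887750	0	0	1	rejection	NA
1	138686941	0	0	1	rejection	NA
1	139295346	0	0	1	rejection	NA
1	140022043	140141190	0	1	rejection	NA
1	140052792	140172769	0	1	rejection	NA
1	0	0	0	1	rejection	NA
7	29490937	0	0	1	rejection	1
1	142944521	0	0	1	rejection	NA
1	142970565	0	0	1	rejection	NA
1	143601266	0	0	1	rejection	NA
1	144487578	0	0	1	rejection	NA
1	144865731	0	0	1	rejection	NA
1	144888036	0	0	1	rejection	NA
1	145285984	0	0	1	rejection	NA
1	145605557	0	0	1	rejection	NA
1	145711971	0	0	1	rejection	NA
1	137462211	0	0	1	rejection	NA
1	146247253	0	0	1	rejection	NA
4	9649533	0	1	0	rejection	NA
4	9885672	0	1	0	rejection	NA
4	10283814	0	1	0	rejection	NA
4	10331873	0	1	0	rejection	NA
4	10355258	0	1	0	rejection	NA
4	10423196	0	1	0	rejection	NA
4	83279186	0	1	1	rejection	NA
6	10893273	0	0	1	rejection	NA
6	10937617	0	0	1	rejection	NA
6	11003757	0	0	1	rejection	NA
6	13664912	0	0	1	rejection	NA
9	9183235	0	1	0	rejection	NA
9	11133568	0	1	0	rejection	NA
9	11355126	0	1	0	rejection	NA
9	11394193	0	1	0	rejection	NA
9	0	0	1	0	rejection	NA
9	11670612	0	1	0	rejection	NA
9	11819832	0	1	0	rejection	NA
14	1404225	0	0	1	rejection	NA
0	0	0	1	1	rejection	NA
4	19490147	0	0	1	acceptance	NA
4	19517211	0	0	1	acceptance	NA
4	19917508	0	0	1	acceptance	NA
18	11099460	0	1	0	acceptance	NA
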