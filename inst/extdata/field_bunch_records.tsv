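bunch	status	actual	predicted
1	matched	unqualified	unqualified
2	matched	unqualified	unqualified
3	matched	unqualified	unqualified
4	matched	unqualified	unqualified
5	matched	qualified	unqualified
6	matched	unqualified	unqualified
7	matched	qualified	unqualified
8	matched	unqualified	unqualified
9	matched	unqualified	unqualified
10	matched	unqualified	unqualified
11	matched	unqualified	qualified
12	matched	qualified	qualified
13	matched	qualified	qualified
14	matched	unqualified	unqualified
15	matched	unqualified	unqualified
16	matched	unqualified	unqualified
17	matched	unqualified	unqualified
18	matched	qualified	unqualified
19	matched	unqualified	unqualified
20	matched	unqualified	unqualified
21	matched	unqualified	unqualified
22	matched	unqualified	unqualified
23	matched	unqualified	unqualified
24	matched	unqualified	unqualified
25	matched	qualified	qualified
26	matched	unqualified	unqualified
27	matched	unqualified	unqualified
28	matched	qualified	qualified
29	matched	qualified	qualified
30	matched	qualified	qualified
31	matched	qualified	qualified
32	matched	unqualified	unqualified
33	matched	unqualified	unqualified
34	matched	unqualified	unqualified
35	matched	qualified	unqualified
36	matched	qualified	qualified
37	matched	unqualified	qualified
38	spurious	NA	unqualified
39	spurious	NA	unqualified
40	missed	unqualified	NA
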