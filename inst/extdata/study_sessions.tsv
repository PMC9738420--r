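participant	condition	perceived_control	frustration	mi_conversion_pct	positive_feedback_pct	fish_caught	fish_lost
1	normal	1	0.17	85	85	0	0
1	augmented_success	0.67	0.33	95	65	0	0
1	input_override	0.5	0.5	100	100	0	0
1	mitigated_failure	0.5	0.33	90	60	0	0
3	normal	1	0	85	85	6	0
3	augmented_success	0.83	0.17	80	60	6	0
3	input_override	0.5	0.17	95	95	8	0
3	mitigated_failure	0.67	0.17	80	55	4	0
4	normal	0.33	1	55	55	3	2
4	augmented_success	0.33	1	15	15	1	5
4	input_override	0.17	1	5	35	2	3
4	mitigated_failure	0	1	10	5	0	4
5	normal	0.33	0.5	60	60	5	1
5	augmented_success	0.33	0.17	60	50	4	1
5	input_override	0.5	0.5	55	70	6	0
5	mitigated_failure	0.33	0.33	70	50	4	1
6	normal	0.67	0.5	50	50	4	2
6	augmented_success	0.5	0.67	15	15	1	5
6	input_override	0.67	0.67	35	50	3	2
6	mitigated_failure	0.67	0.33	30	25	1	2
7	normal	1	0.17	85	85	8	0
7	augmented_success	0.33	0.5	90	55	5	2
7	input_override	0.67	0.5	95	100	7	0
7	mitigated_failure	0.33	0.5	50	40	2	1
8	normal	0.17	0.67	25	25	1	4
8	augmented_success	0.33	0.67	50	35	1	4
8	input_override	0.33	0.33	30	55	5	2
8	mitigated_failure	0.33	0.33	25	25	1	3
9	normal	0.83	0.33	100	100	8	0
9	augmented_success	0.17	0.83	30	20	0	5
9	input_override	0.5	0.5	95	95	8	0
9	mitigated_failure	0.67	0.67	75	55	5	0
10	normal	0.67	0.67	65	65	4	0
10	augmented_success	0.33	0.33	35	25	2	4
10	input_override	0.5	0.17	15	40	2	3
10	mitigated_failure	0.33	0.5	30	30	1	2
11	normal	0	1	0	0	0	6
11	augmented_success	0	1	15	15	1	5
11	input_override	0	1	5	35	2	4
11	mitigated_failure	0.17	1	25	20	1	3
12	normal	0.67	0.17	70	70	6	0
12	augmented_success	0.17	0.5	85	70	8	0
12	input_override	0.33	0.67	50	60	4	1
12	mitigated_failure	0	0.83	80	65	5	0
13	normal	1	0	80	80	6	0
13	augmented_success	0.5	0.17	75	50	4	2
13	input_override	0.67	0.83	90	95	7	0
13	mitigated_failure	0.67	0	75	55	4	0
14	normal	0	0.83	15	15	1	5
14	augmented_success	0.33	0.67	35	30	2	3
14	input_override	0	0.5	30	50	3	2
14	mitigated_failure	NA	NA	NA	NA	NA	NA
15	normal	0.33	0.67	25	25	2	4
15	augmented_success	0.67	0.33	65	50	6	2
15	input_override	0.67	0.5	65	75	7	0
15	mitigated_failure	0.5	0.5	55	50	3	1
16	normal	0.5	0.33	35	35	2	3
16	augmented_success	1	0.17	45	45	5	3
16	input_override	0.83	0.33	40	65	4	1
16	mitigated_failure	0.67	0.33	15	15	1	3
17	normal	0.5	0.83	65	65	5	0
17	augmented_success	0.67	0.67	45	45	6	2
17	input_override	0.33	0.83	30	60	4	1
17	mitigated_failure	0.17	1	40	25	1	2
18	normal	0.67	0.5	75	75	7	0
18	augmented_success	0.17	0.67	85	60	5	2
18	input_override	0.33	0.5	65	70	5	0
18	mitigated_failure	0.33	0.5	85	55	4	0
19	normal	0.5	0.17	60	60	4	2
19	augmented_success	0.67	0.17	55	45	5	2
19	input_override	0.33	0.5	45	60	4	2
19	mitigated_failure	0.67	0	60	45	3	1
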