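activity	met_value	category
sitting quietly	1.3	sedentary
standing, light office work	1.8	light
walking, 2.0 mph, slow	2.8	light
walking the dog	3.0	moderate
walking, 3.0 mph, moderate pace	3.5	moderate
brisk walking, 4.0 mph	5.0	moderate
gardening, general	3.8	moderate
housework, vigorous effort	3.5	moderate
cycling, leisure, <10 mph	4.0	moderate
cycling, 10-12 mph	6.0	vigorous
cycling, 12-14 mph	8.0	vigorous
swimming, leisurely	6.0	vigorous
swimming laps, moderate effort	7.0	vigorous
jogging, general	7.0	vigorous
running, 6 mph	9.8	vigorous
stair climbing, slow	4.0	moderate
aerobics, general	7.3	vigorous
yoga, hatha	2.5	light
strength training, general	3.5	moderate
tennis, doubles	6.0	vigorous
dancing, general	4.5	moderate
golf, walking, carrying clubs	4.3	moderate
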