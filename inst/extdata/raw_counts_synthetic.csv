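"animal_id","sex","condition","region","bregma_mm","left_count","right_count"
"m_n_1","male","naive","PL",-1.2,44,42
"m_n_1","male","naive","PL",-0.9,38,42
"m_n_1","male","naive","PL",-0.6,44,44
"m_n_1","male","naive","ILA",-1.2,26,32
"m_n_1","male","naive","ILA",-0.9,,28
"m_n_1","male","naive","ILA",-0.6,30,36
"m_n_1","male","naive","LA",-1.2,55,49
"m_n_1","male","naive","LA",-0.9,48,41
"m_n_1","male","naive","LA",-0.6,64,57
"m_n_1","male","naive","BLA",-1.2,62,56
"m_n_1","male","naive","BLA",-0.9,60,63
"m_n_1","male","naive","BLA",-0.6,42,51
"m_n_1","male","naive","CEA",-1.2,,41
"m_n_1","male","naive","CEA",-0.9,41,33
"m_n_1","male","naive","CEA",-0.6,46,47
"m_n_1","male","naive","CA1",-1.2,43,32
"m_n_1","male","naive","CA1",-0.9,38,25
"m_n_1","male","naive","CA1",-0.6,34,27
"m_n_1","male","naive","PVT",-1.2,65,62
"m_n_1","male","naive","PVT",-0.9,68,65
"m_n_1","male","naive","PVT",-0.6,59,65
"m_n_1","male","naive","GP",-1.2,47,47
"m_n_1","male","naive","GP",-0.9,49,40
"m_n_1","male","naive","GP",-0.6,40,41
"m_n_2","male","naive","PL",-1.2,47,45
"m_n_2","male","naive","PL",-0.9,48,39
"m_n_2","male","naive","PL",-0.6,54,49
"m_n_2","male","naive","ILA",-1.2,27,21
"m_n_2","male","naive","ILA",-0.9,22,25
"m_n_2","male","naive","ILA",-0.6,17,23
"m_n_2","male","naive","LA",-1.2,46,45
"m_n_2","male","naive","LA",-0.9,42,41
"m_n_2","male","naive","LA",-0.6,37,33
"m_n_2","male","naive","BLA",-1.2,37,48
"m_n_2","male","naive","BLA",-0.9,,38
"m_n_2","male","naive","BLA",-0.6,41,50
"m_n_2","male","naive","CEA",-1.2,42,33
"m_n_2","male","naive","CEA",-0.9,48,39
"m_n_2","male","naive","CEA",-0.6,46,51
"m_n_2","male","naive","CA1",-1.2,36,35
"m_n_2","male","naive","CA1",-0.9,42,48
"m_n_2","male","naive","CA1",-0.6,50,36
"m_n_2","male","naive","PVT",-1.2,48,44
"m_n_2","male","naive","PVT",-0.9,47,54
"m_n_2","male","naive","PVT",-0.6,48,58
"m_n_2","male","naive","GP",-1.2,33,36
"m_n_2","male","naive","GP",-0.9,,24
"m_n_2","male","naive","GP",-0.6,42,42
"f_n_1","female","naive","PL",-1.2,29,38
"f_n_1","female","naive","PL",-0.9,37,42
"f_n_1","female","naive","PL",-0.6,,31
"f_n_1","female","naive","ILA",-1.2,32,37
"f_n_1","female","naive","ILA",-0.9,36,24
"f_n_1","female","naive","ILA",-0.6,27,28
"f_n_1","female","naive","LA",-1.2,58,59
"f_n_1","female","naive","LA",-0.9,60,60
"f_n_1","female","naive","LA",-0.6,58,53
"f_n_1","female","naive","BLA",-1.2,33,35
"f_n_1","female","naive","BLA",-0.9,37,45
"f_n_1","female","naive","BLA",-0.6,34,28
"f_n_1","female","naive","CEA",-1.2,27,31
"f_n_1","female","naive","CEA",-0.9,45,35
"f_n_1","female","naive","CEA",-0.6,32,21
"f_n_1","female","naive","CA1",-1.2,27,36
"f_n_1","female","naive","CA1",-0.9,28,25
"f_n_1","female","naive","CA1",-0.6,30,22
"f_n_1","female","naive","PVT",-1.2,50,43
"f_n_1","female","naive","PVT",-0.9,32,40
"f_n_1","female","naive","PVT",-0.6,52,41
"f_n_1","female","naive","GP",-1.2,41,28
"f_n_1","female","naive","GP",-0.9,36,32
"f_n_1","female","naive","GP",-0.6,43,40
"f_n_2","female","naive","PL",-1.2,22,35
"f_n_2","female","naive","PL",-0.9,29,22
"f_n_2","female","naive","PL",-0.6,33,36
"f_n_2","female","naive","ILA",-1.2,26,25
"f_n_2","female","naive","ILA",-0.9,39,30
"f_n_2","female","naive","ILA",-0.6,29,25
"f_n_2","female","naive","LA",-1.2,56,45
"f_n_2","female","naive","LA",-0.9,48,40
"f_n_2","female","naive","LA",-0.6,57,55
"f_n_2","female","naive","BLA",-1.2,35,34
"f_n_2","female","naive","BLA",-0.9,26,26
"f_n_2","female","naive","BLA",-0.6,37,32
"f_n_2","female","naive","CEA",-1.2,23,33
"f_n_2","female","naive","CEA",-0.9,32,25
"f_n_2","female","naive","CEA",-0.6,30,30
"f_n_2","female","naive","CA1",-1.2,49,63
"f_n_2","female","naive","CA1",-0.9,59,49
"f_n_2","female","naive","CA1",-0.6,46,50
"f_n_2","female","naive","PVT",-1.2,46,46
"f_n_2","female","naive","PVT",-0.9,45,39
"f_n_2","female","naive","PVT",-0.6,36,46
"f_n_2","female","naive","GP",-1.2,69,71
"f_n_2","female","naive","GP",-0.9,63,57
"f_n_2","female","naive","GP",-0.6,61,76
"m_t_1","male","trained","PL",-1.2,70,67
"m_t_1","male","trained","PL",-0.9,70,85
"m_t_1","male","trained","PL",-0.6,69,77
"m_t_1","male","trained","ILA",-1.2,84,92
"m_t_1","male","trained","ILA",-0.9,108,100
"m_t_1","male","trained","ILA",-0.6,105,84
"m_t_1","male","trained","LA",-1.2,74,96
"m_t_1","male","trained","LA",-0.9,82,71
"m_t_1","male","trained","LA",-0.6,70,77
"m_t_1","male","trained","BLA",-1.2,84,94
"m_t_1","male","trained","BLA",-0.9,84,92
"m_t_1","male","trained","BLA",-0.6,67,72
"m_t_1","male","trained","CEA",-1.2,54,66
"m_t_1","male","trained","CEA",-0.9,62,57
"m_t_1","male","trained","CEA",-0.6,62,66
"m_t_1","male","trained","CA1",-1.2,65,63
"m_t_1","male","trained","CA1",-0.9,77,66
"m_t_1","male","trained","CA1",-0.6,66,81
"m_t_1","male","trained","PVT",-1.2,64,55
"m_t_1","male","trained","PVT",-0.9,84,67
"m_t_1","male","trained","PVT",-0.6,64,84
"m_t_1","male","trained","GP",-1.2,135,131
"m_t_1","male","trained","GP",-0.9,127,116
"m_t_1","male","trained","GP",-0.6,115,112
"f_t_1","female","trained","PL",-1.2,83,83
"f_t_1","female","trained","PL",-0.9,,79
"f_t_1","female","trained","PL",-0.6,87,88
"f_t_1","female","trained","ILA",-1.2,40,49
"f_t_1","female","trained","ILA",-0.9,43,47
"f_t_1","female","trained","ILA",-0.6,43,40
"f_t_1","female","trained","LA",-1.2,100,100
"f_t_1","female","trained","LA",-0.9,96,96
"f_t_1","female","trained","LA",-0.6,114,93
"f_t_1","female","trained","BLA",-1.2,78,91
"f_t_1","female","trained","BLA",-0.9,126,82
"f_t_1","female","trained","BLA",-0.6,84,101
"f_t_1","female","trained","CEA",-1.2,55,57
"f_t_1","female","trained","CEA",-0.9,74,62
"f_t_1","female","trained","CEA",-0.6,70,75
"f_t_1","female","trained","CA1",-1.2,,83
"f_t_1","female","trained","CA1",-0.9,111,86
"f_t_1","female","trained","CA1",-0.6,106,103
"f_t_1","female","trained","PVT",-1.2,51,53
"f_t_1","female","trained","PVT",-0.9,73,56
"f_t_1","female","trained","PVT",-0.6,60,59
"f_t_1","female","trained","GP",-1.2,90,72
"f_t_1","female","trained","GP",-0.9,72,80
"f_t_1","female","trained","GP",-0.6,75,69
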