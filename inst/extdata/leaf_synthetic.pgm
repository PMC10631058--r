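P2
32 32
255
12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 95 124 140 122 84 60 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 67 62 76 106 137 145 132 117 101 94 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 100 76 68 67 77 107 141 165 170 148 127 142 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 117 93 87 76 62 74 111 153 169 146 119 127 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 160 131 110 106 89 60 60 85 122 133 110 86 87 102 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 169 152 127 111 104 84 60 60 82 108 110 86 64 60 63 86 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 137 117 101 92 85 73 68 79 95 106 102 84 64 60 60 90 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 101 91 88 87 84 84 95 105 100 92 89 83 74 69 84 119 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 112 99 103 114 117 113 117 134 133 103 77 74 78 81 92 120 150 159 12 12 12 12 12 12 12
12 12 12 12 12 12 12 136 130 143 158 155 142 148 173 170 127 89 81 85 91 112 143 159 152 12 12 12 12 12 12 12
12 12 12 12 12 12 12 173 173 186 193 180 159 162 191 195 157 120 111 111 112 126 144 147 141 12 12 12 12 12 12 12
12 12 12 12 12 12 12 207 214 220 213 190 166 160 176 182 159 136 132 134 133 138 140 131 129 12 12 12 12 12 12 12
12 12 12 12 12 12 12 237 246 239 212 182 162 149 146 144 133 121 122 129 136 142 134 114 104 12 12 12 12 12 12 12
12 12 12 12 12 12 12 247 250 231 189 156 146 139 127 116 106 96 94 106 123 133 121 95 76 12 12 12 12 12 12 12
12 12 12 12 12 12 12 213 210 188 150 125 128 135 130 116 101 87 83 95 112 120 109 87 73 12 12 12 12 12 12 12
12 12 12 12 12 12 12 147 143 132 112 102 116 140 147 134 116 100 95 102 107 105 101 99 98 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 90 92 88 86 106 138 154 146 131 119 113 112 104 94 102 122 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 76 83 80 76 91 117 132 134 133 129 119 107 92 86 107 138 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 93 91 79 74 83 97 105 116 127 124 104 78 63 72 106 143 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 90 73 78 98 110 115 127 134 121 86 60 60 60 99 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 69 89 126 149 160 168 165 140 95 60 60 60 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 93 116 154 180 191 193 187 163 119 67 60 60 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 164 180 186 182 178 176 164 134 95 77 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 168 149 144 150 152 139 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12
12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12 12
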