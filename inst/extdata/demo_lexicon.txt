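the 22038615
be 12545825
and 10741073
of 10343885
a 10144200
in 6996437
to 6332195
have 4303955
it 3872477
i 3978265
that 3430996
for 3281454
you 3081151
he 2909254
with 2683014
on 2485306
do 2573587
say 1915138
this 1885366
they 1865580
at 1767638
but 1776767
we 1820935
his 1801708
from 1635914
not 1638883
by 1577059
she 1484869
or 1379320
as 1296879
what 1181023
go 1151045
their 1083029
can 1022775
who 1018283
get 992596
if 932542
would 907403
her 860509
all 825591
my 919821
make 857168
about 874406
know 851017
will 824568
am 645183
up 795534
one 701273
time 652527
there 680724
year 605177
so 693154
think 559596
when 579119
which 538599
them 527715
some 519272
me 564100
people 516268
take 487363
out 479073
into 441067
just 455795
see 441688
him 434061
your 429115
come 409767
could 396871
now 389023
than 368920
like 386147
other 342301
how 339185
then 335518
its 308105
our 309066
two 284494
more 348650
these 274376
want 273312
way 268046
look 264137
first 258369
also 252586
new 249969
because 243618
day 242488
use 242185
no 243110
man 237391
find 232038
here 228088
thing 226966
give 224768
many 222229
well 216260
best 100657
friend 81512
friends 75342
love 166911
sad 22058
happy 57110
you 3081151
soul 21962
life 186344
heart 63430
hope 51963
dream 20199
dreams 15061
good 201104
bad 69199
sorry 28561
miss 21266
mom 18455
dad 17300
family 103924
world 145382
god 43178
peace 19309
forgive 5541
thank 26700
please 27324
write 30983
something 115119
everyone 41625
never 116501
always 105144
end 98133
pain 27266
tired 14364
alone 30135
again 103170
leave 56068
gone 36179
home 123596
away 111968
let 115301
us 128896
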