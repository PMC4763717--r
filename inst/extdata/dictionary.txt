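# compact english word list (templates + common words)
 all afte
 fo
 for 
 sa
 ten 
 the
 the 
 the c
 the g
 wh
} a
} is ge
} o
} of
a
about
after
again
all
also
amazing
an
and
any
ar
arch
are
as
at
aus
awareness
back
be
beautiful
because
been
before
being
between
book
both
but
by
can
cannot
case
cat
check
child
coffee
com
come
confirmed
could
d up 
day
diagnosed
did
ding 
dinner
do
doctor
does
dog
dot
down
e
each
ect
en 
er
erm
erm}
erm} 
erm} af
erm} be
erm} res
erm} s
erm} sym
even
everyone
explained
eye
fact
few
find
first
for
friends
from
gain
gain 
game
gave
get
give
going
good
got
grandma
great
group
had
hand
has
have
he
her
highway
him
his
horoscope
hospital
house
how
i is tre
if
in
into
is
it
ita
its
just
know
lake
last
last 
life
like
little
living
lo
long
look
lovely
m} i
made
make
man
many
may
me
medication
mo
more
morning
most
movie
much
must
my
n is c
named
nearly
never
new
no
not
now
number
nurse
of
off
old
on
one
only
or
other
our
out
over
own
part
people
place
playing
point
pure
pure g
raising
reading
really
recipe
right
run
said
same
sat
say
says
see
she
should
since
slash
so
some
song
start
still
such
sunset
take
taking
talk
tell
terrible
than
thanks
that
the
their
them
then
there
these
they
think
this
this 
those
three
through
time
ting 
tinyurl
to
toms f
tonight
too
traffic
trains
two
under
up
us
use
very
very mo
visit
w
wait
want
was
watching
water
way
we
week
weekend
well
went
were
what
when
where
which
while
who
why
will
with
woman
work
world
would
year
yes
you
your
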